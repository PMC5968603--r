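year,population_total,ply_headcount,missing_workers,ft_no_arth_count,lost_income_m,extra_welfare_m,lost_tax_m,projected_gdp_m,lost_gdp_m,p_ft_pct,p_pt_pct
2015,5945000,54000,53000,2912000,1516,847,352,1483861,6208,71.68,25.40
2020,6374000,58000,56000,3169000,1756,912,394,1678852,6852,71.46,26.02
2025,6677000,59000,58000,3336000,2086,933,473,1899467,7535,71.24,26.37
2030,7130000,61000,59000,3600000,2406,959,549,2149073,8191,71.17,26.49
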