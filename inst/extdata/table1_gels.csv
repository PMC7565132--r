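# Literature observations of spontaneous particle penetration into bio-gels.
# Diameters in nm; cl = liquid volume fraction; l_nm = repeat-unit length.
# Range cells are written lo;hi and resolved to their midpoint by default.
# Mucus rows: cl = 95%, mucin repeat unit l = 16-20 nm (midpoint 18 nm).
# Biofilm rows: only ranges are reported for cl (87-99%) and l (0.07-1.5 nm);
# matching the published repeat-unit counts (1862/620 for P. fluorescens)
# would require point values near J^(1/3)*l ~ 1.2 nm that were never stated,
# so biofilm n estimates from the midpoints are indicative only.
name,d_min_nm,d_max_nm,d_avg_nm,cl,l_nm,m_values
Respiratory mucus,60,300,140,0.95,16;20,3;4
Intestinal mucus,20,500,210,0.95,16;20,3;4
Cervicovaginal mucus,50,1800,340,0.95,16;20,3;4
Pseudomonas fluorescens biofilm,10,50,30,0.87;0.99,0.07;1.5,3;4
Streptococcus mutans biofilm,0.2,2.5,2.0,0.87;0.99,0.07;1.5,3;4
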