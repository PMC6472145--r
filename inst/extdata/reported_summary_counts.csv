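table,group,n_journals,n_articles_with_p,n_pvalues,pvalues_per_article,n_inrange,inrange_per_article,pct_marginal,pm_lower,pm_upper,pct_articles_marginal,pam_lower,pam_upper
discipline,all,70,44200,777596,17.59,42504,0.96,39.60,39.13,40.06,19.63,19.26,20.00
discipline,clinical,30,15216,195999,12.88,10173,0.67,30.08,29.19,30.97,12.22,11.70,12.74
discipline,cognitive,10,7882,161614,20.50,9343,1.19,39.49,38.50,40.49,23.59,22.65,24.52
discipline,developmental,8,5624,84946,15.10,4181,0.74,37.72,36.25,39.19,17.37,16.38,18.36
discipline,educational,10,9808,143178,14.60,6691,0.68,34.69,33.55,35.83,14.07,13.38,14.76
discipline,experimental,19,15387,334743,21.75,18907,1.23,40.65,39.95,41.35,24.55,23.87,25.23
discipline,forensic,4,2075,26527,12.78,1271,0.61,33.91,31.31,36.51,11.42,10.05,12.79
discipline,health,25,11054,138266,12.51,6802,0.62,31.58,30.47,32.68,11.51,10.91,12.10
discipline,organizational,13,10514,210732,20.04,12255,1.17,45.38,44.50,46.26,24.20,23.38,25.01
discipline,social,25,13746,266015,19.35,15736,1.14,44.47,43.69,45.25,25.32,24.60,26.05
journal,jpsp,1,4073,114872,28.20,8001,1.96,49.88,48.79,50.98,41.84,40.32,43.35
journal,devpsych,1,2806,49201,17.53,2541,0.91,39.71,37.81,41.61,21.74,20.21,23.27
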