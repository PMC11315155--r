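compound_id,threshold_ug_per_L,medium,oav_YJ,oav_JJ,oav_NEH,oav_GLS,oav_SKM,oav_KJS,oav_XH,oav_CC,oav_ZY
octanoic_acid,500.0,unspecified,<1,1.10,-,-,-,-,-,-,<1
decanoic_acid,130.0,unspecified,<1,<1,-,-,-,-,-,<1,2.04
ethanol,10000.0,unspecified,<1,<1,<1,<1,<1,1.16,<1,<1,1.03
phenylethyl_alcohol,250.0,unspecified,4.91,10.81,9.27,27.14,27.22,36.64,24.85,17.62,39.93
isoamyl_alcohol,250.0,unspecified,4.25,3.12,2.90,3.29,2.80,5.96,4.84,6.95,12.83
2_nonanol,58.0,unspecified,<1,1.41,-,-,-,-,<1,-,<1
1_nonanol,34.0,unspecified,-,-,-,-,-,-,-,<1,1.74
benzaldehyde,350.0,unspecified,<1,<1,<1,16.45,10.93,11.07,<1,-,-
benzeneacetaldehyde,4.0,unspecified,<1,12.63,48.03,-,-,11.68,14.33,-,-
3_methylbutanal,120.0,unspecified,-,-,2.48,-,-,-,-,-,-
5_methyl_2_furaldehyde,16.0,unspecified,-,-,2.52,-,-,-,-,-,-
methacrylaldehyde,25.0,unspecified,-,-,-,7.77,8.24,5.64,-,-,-
ethyl_acetate,5.0,unspecified,281.40,338.91,378.78,357.32,176.60,354.08,373.77,938.28,253.05
ethyl_octanoate,5.0,unspecified,231.97,344.08,66.53,54.15,36.20,63.37,238.43,556.96,255.22
ethyl_decanoate,200.0,unspecified,2.28,2.02,1.39,-,<1,<1,<1,5.22,1.81
diethyl_succinate,1200.0,unspecified,<1,<1,<1,1.23,<1,2.74,1.52,2.13,4.39
2_octyl_acetate,38.0,unspecified,2.17,2.89,3.03,4.32,3.20,4.27,4.68,1.60,<1
isoamyl_acetate,30.0,unspecified,2.39,4.88,2.78,1.16,<1,<1,3.64,3.14,3.03
isoamyl_lactate,3.0,unspecified,11.98,133.47,-,10.74,5.65,21.85,16.92,5.39,28.97
ethyl_hexanoate,14.0,unspecified,2.18,-,-,-,-,-,-,-,-
ethyl_isobutyrate,5.6,unspecified,4.138,3.914,16.379,-,-,-,2.820,10.168,-
ethyl_butyrate,20.0,unspecified,<1,1.82,1.07,1.38,-,<1,1.10,<1,<1
ethyl_phenylacetate,73.0,unspecified,<1,<1,<1,3.91,2.45,4.09,<1,<1,<1
ethyl_2_methylbutyrate,18.0,unspecified,<1,1.39,-,-,-,-,-,<1,<1
ethyl_heptanoate,2.0,unspecified,1.22,4.30,1.63,20.91,3.83,20.29,4.97,-,-
gamma_undecalactone,4.0,unspecified,<1,1.45,3.07,-,-,15.08,-,-,-
ethyl_isovalerate,3.0,unspecified,-,4.29,39.38,14.68,5.23,-,-,2.07,2.25
ethyl_benzoate,500.0,unspecified,-,-,-,1.15,<1,<1,-,-,-
ethyl_valerate,5.0,unspecified,-,-,-,3.58,-,3.53,-,-,-
gamma_nonalactone,65.0,unspecified,-,-,-,-,-,1.25,-,-,-
2_methylbutyl_acetate,11.0,unspecified,2.30,-,-,-,-,-,-,-,-
styrene,100.0,unspecified,-,-,-,-,-,1.16,-,-,-
2_ethoxymethyl_furan,11.0,unspecified,1.91,9.18,1.10,-,1.51,-,-,<1,1.59
1_1_6_trimethyl_1_2_dihydronaphthalene,2.5,unspecified,-,-,-,-,-,-,-,9.23,8.61
4_ethyl_2_methoxyphenol,6.9,unspecified,3.67,12.48,-,-,-,-,7.68,-,-
4_ethylphenol,51.0,unspecified,<1,1.75,<1,-,-,-,-,1.95,<1
alpha_ionone,8.0,unspecified,-,-,-,-,-,-,-,20.29,12.68
linalool,6.0,unspecified,-,-,-,-,-,-,-,-,2.16
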