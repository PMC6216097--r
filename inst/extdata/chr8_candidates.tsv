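symbol	chr	start_mb	end_mb	coding_variant	cis_eqtl	correlated	prior_phenotype
Arhgef10	8	4.92	5.04	TRUE	TRUE	TRUE	TRUE
Kbtbd11	8	15.02	15.06	TRUE	TRUE	TRUE	FALSE
Myom2	8	15.06	15.17	TRUE	FALSE	TRUE	TRUE
Csmd1	8	15.89	17.58	TRUE	TRUE	TRUE	TRUE
Dlgap2	8	14.06	14.84	TRUE	TRUE	TRUE	TRUE
Cln8	8	14.88	14.91	TRUE	FALSE	FALSE	TRUE
Abhd13	8	9.97	9.99	TRUE	TRUE	FALSE	TRUE
Fam155a	8	9.60	9.90	TRUE	FALSE	FALSE	TRUE
Col4a1	8	11.19	11.31	TRUE	FALSE	FALSE	TRUE
Col4a2	8	11.29	11.45	TRUE	FALSE	FALSE	TRUE
Arhgef7	8	11.77	11.92	TRUE	FALSE	FALSE	TRUE
Tfdp1	8	13.36	13.40	TRUE	FALSE	FALSE	TRUE
2900016B01Rik	8	13.98	14.00	TRUE	TRUE	TRUE	FALSE
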