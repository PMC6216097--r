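symbol	chr	start_mb	end_mb	coding_variant	cis_eqtl	correlated	prior_phenotype
Cdh4	2	179.67	180.12	TRUE	FALSE	FALSE	TRUE
Taf4	2	179.92	179.98	TRUE	FALSE	FALSE	TRUE
Psma7	2	180.03	180.04	TRUE	FALSE	FALSE	TRUE
Ss18l1	2	180.06	180.09	TRUE	TRUE	FALSE	TRUE
Gtpbp5	2	180.22	180.24	TRUE	TRUE	TRUE	FALSE
Osbpl2	2	180.27	180.31	TRUE	TRUE	FALSE	TRUE
Adrm1	2	180.33	180.34	TRUE	FALSE	FALSE	TRUE
Lama5	2	180.35	180.40	TRUE	TRUE	FALSE	TRUE
1600027N09Rik	2	180.41	180.42	TRUE	TRUE	FALSE	FALSE
Ntsr1	2	180.50	180.55	TRUE	FALSE	FALSE	TRUE
Ogfr	2	180.58	180.60	TRUE	TRUE	TRUE	FALSE
Col9a3	2	180.60	180.63	TRUE	FALSE	FALSE	TRUE
Tcfl5	2	180.63	180.65	TRUE	TRUE	FALSE	FALSE
Dido1	2	180.66	180.69	TRUE	TRUE	FALSE	TRUE
Slco4a1	2	180.70	180.73	TRUE	FALSE	TRUE	FALSE
Slc17a9	2	180.73	180.74	TRUE	FALSE	TRUE	TRUE
Bhlhe23	2	180.77	180.78	TRUE	FALSE	FALSE	TRUE
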