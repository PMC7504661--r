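drug1,drug2,targets1,targets2,score,cell_line
Erlotinib,Dasatinib,EGFR,EPHA2,34.44,IGROV1
Gefitinib,Dasatinib,EGFR,EPHA2,23.22,IGROV1
Vandetanib,Dasatinib,EGFR,EPHA2,18.44,IGROV1
Dasatinib,Tamoxifen,EPHA2,"PRKCZ, PRKCI",16.78,IGROV1
Lapatinib,Sirolimus,"ERBB2, EGFR",MTOR,14.00,IGROV1
Vandetanib,Everolimus,EGFR,MTOR,13.56,IGROV1
Celecoxib,Dasatinib,PDPK1,EPHA2,13.11,IGROV1
Lapatinib,Everolimus,"ERBB2, EGFR",MTOR,12.44,IGROV1
Sirolimus,Tamoxifen,MTOR,"PRKCZ, PRKCI",11.67,IGROV1
Lapatinib,Dasatinib,"ERBB2, EGFR",EPHA2,11.00,IGROV1
Gefitinib,Everolimus,EGFR,MTOR,10.78,IGROV1
Dasatinib,Imatinib,EPHA2,PDGFRA,10.56,IGROV1
Celecoxib,Vandetanib,PDPK1,EGFR,9.11,IGROV1
Sirolimus,Vandetanib,MTOR,EGFR,8.78,IGROV1
Erlotinib,Tamoxifen,EGFR,"PRKCZ, PRKCI",8.33,IGROV1
Dasatinib,Tamoxifen,EPHA2,"PRKCZ, PRKCI",11.33,OVCAR-3
Sirolimus,Everolimus,MTOR,MTOR,9.56,OVCAR-3
Celecoxib,Dasatinib,PDPK1,EPHA2,9.44,OVCAR-3
Thalidomide,Dasatinib,TNF,EPHA2,8.89,OVCAR-3
Sirolimus,Gefitinib,MTOR,EGFR,10.56,OVCAR-4
Gefitinib,Everolimus,EGFR,MTOR,9.44,OVCAR-4
Lapatinib,Sirolimus,"ERBB2, EGFR",MTOR,9.44,OVCAR-4
Vandetanib,Tamoxifen,EGFR,"PRKCZ, PRKCI",9.33,OVCAR-5
Dasatinib,Tamoxifen,EPHA2,"PRKCZ, PRKCI",14.78,SK-OV-3
Everolimus,Tamoxifen,MTOR,"PRKCZ, PRKCI",11.78,SK-OV-3
Lapatinib,Dasatinib,"ERBB2, EGFR",EPHA2,10.11,SK-OV-3
Celecoxib,Dasatinib,PDPK1,EPHA2,9.56,SK-OV-3
Gefitinib,Dasatinib,EGFR,EPHA2,9.11,SK-OV-3
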