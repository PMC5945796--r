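quantity,dxa_tscore,qct_ssfe,dual
n_referred,1000,1000,1000
n_treated,367,602,633
n_untreated,633,398,286
fractures_treated,147,241,253
fractures_untreated,316,199,143
fractures_total,463,440,396
assessment_cost,1255000,2610000,1899184
treatment_cost,2644898,4334694,4555102
fracture_direct_cost,7552151,7169553,6454261
total_direct,11452049,14114247,12908547
fracture_indirect_cost,4801282,4558045,4103298
total_full,16253331,18672292,17011845
direct_saved,NA,-2662197.96,-1456497.96
full_saved,NA,-2418961.22,-758514.29
fractures_avoided,NA,23,67
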