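jurisdiction,category,basis,mean,sd,cv
UK,hospitalization,per_person,3225,7132,2.21
Italy,hospitalization,per_person,2486,10689,4.30
France,hospitalization,per_person,6262,6553,1.05
UK,hospice,per_person,2394,4247,1.77
Italy,hospice,per_person,185,396,2.14
France,hospice,per_person,298,511,1.72
UK,outpatient,per_person,587,275,0.47
Italy,outpatient,per_person,29,15,0.51
France,outpatient,per_person,28,31,1.11
UK,hospitalization,per_user,11437,13432,1.17
Italy,hospitalization,per_user,3306,2209,0.67
France,hospitalization,per_user,11469,8859,0.77
UK,hospice,per_user,10363,5103,0.49
Italy,hospice,per_user,185,94,0.51
France,hospice,per_user,3429,2079,0.61
UK,outpatient,per_user,782,314,0.40
Italy,outpatient,per_user,72,28,0.39
France,outpatient,per_user,59,15,0.26
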