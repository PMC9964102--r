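factor,group,coefficient,std_error,p_value
systolic_bp,under 50,0.70,0.153,4.52e-06
systolic_bp,50 to 59,0.54,0.081,4.00e-11
systolic_bp,60 to 69,0.50,0.053,2.00e-16
systolic_bp,70 plus,0.17,0.037,2.27e-06
diastolic_bp,under 50,0.55,0.143,0.0001
diastolic_bp,50 to 59,0.55,0.083,5.11e-11
diastolic_bp,60 to 69,0.39,0.052,9.32e-14
diastolic_bp,70 plus,0.24,0.038,8.6e-11
total_cholesterol,under 50,0.36,0.143,0.01
total_cholesterol,50 to 59,0.16,0.090,0.08
total_cholesterol,60 to 69,0.17,0.063,0.006
total_cholesterol,70 plus,0.07,0.050,0.19
bmi,under 50,0.32,0.136,0.02
bmi,50 to 59,0.32,0.078,4.03e-05
bmi,60 to 69,0.06,0.050,0.27
bmi,70 plus,0.06,0.037,0.12
sex,under 50,0.22,0.271,0.42
sex,50 to 59,0.06,0.155,0.72
sex,60 to 69,-0.08,0.100,0.41
sex,70 plus,0.15,0.074,0.05
atrial_fibrillation,under 50,0.48,0.523,0.36
atrial_fibrillation,50 to 59,1.40,0.381,0.0002
atrial_fibrillation,60 to 69,1.94,0.241,9.59e-16
atrial_fibrillation,70 plus,2.64,0.155,2e-16
hbp_treatment,under 50,0.66,0.460,0.15
hbp_treatment,50 to 59,0.21,0.201,0.31
hbp_treatment,60 to 69,0.23,0.104,0.03
hbp_treatment,70 plus,0.11,0.074,0.15
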