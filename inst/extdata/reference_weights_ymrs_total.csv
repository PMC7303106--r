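predictor,mu_mean,mu_sd,mu_ci_low,mu_ci_high,abs_t,tau_mean,tau_sd,tau_ci_low,tau_ci_high
intercept,3.10,0.68,1.79,4.46,4.59,4.35,0.50,3.48,5.40
mood_positive,12.83,1.90,9.09,16.53,6.75,0.57,0.42,0.02,1.57
mood_negative,3.42,1.30,0.87,5.99,2.63,0.66,0.46,0.03,1.68
irritability,1.31,0.69,-0.05,2.68,1.90,0.71,0.47,0.04,1.73
mixed_mood,1.02,0.62,-0.20,2.21,1.65,0.54,0.36,0.03,1.34
stress,1.15,0.70,-0.21,2.54,1.65,1.24,0.53,0.12,2.18
sleep_positive,-2.69,1.84,-6.30,0.84,1.46,0.40,0.30,0.01,1.12
activity,-0.78,0.56,-1.88,0.30,1.39,0.63,0.41,0.03,1.52
medicine_changed,0.46,0.71,-0.99,1.81,0.64,0.80,0.48,0.05,1.76
cognitive,0.41,0.69,-0.92,1.78,0.59,0.94,0.54,0.05,1.99
anxiety,0.18,0.80,-1.40,1.73,0.23,0.69,0.48,0.03,1.76
sleep_negative,0.30,1.50,-2.63,3.26,0.20,0.43,0.32,0.02,1.17
alcohol,0.05,0.93,-1.77,1.86,0.06,0.39,0.30,0.02,1.11
medicine_omitted,-0.02,0.90,-1.78,1.75,0.02,0.41,0.31,0.01,1.15
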