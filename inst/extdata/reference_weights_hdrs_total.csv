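predictor,mu_mean,mu_sd,mu_ci_low,mu_ci_high,abs_t,tau_mean,tau_sd,tau_ci_low,tau_ci_high
intercept,6.43,0.66,5.13,7.73,9.67,4.10,0.50,3.23,5.19
mood_negative,-9.11,1.40,-11.94,-6.43,6.51,0.56,0.40,0.02,1.50
sleep_negative,-6.48,1.66,-9.72,-3.19,3.89,0.42,0.31,0.02,1.16
mixed_mood,2.11,0.67,0.79,3.42,3.15,0.44,0.32,0.02,1.20
anxiety,2.26,0.86,0.58,3.96,2.63,0.38,0.28,0.02,1.06
medicine_changed,-1.81,0.71,-3.19,-0.40,2.55,0.35,0.27,0.01,0.99
cognitive,1.09,0.73,-0.35,2.48,1.50,0.43,0.32,0.02,1.19
mood_positive,-2.80,1.94,-6.59,0.94,1.44,0.42,0.32,0.02,1.19
sleep_positive,2.83,2.05,-1.09,6.90,1.38,0.41,0.31,0.02,1.15
activity,0.53,0.61,-0.66,1.71,0.88,0.50,0.35,0.02,1.29
stress,0.56,0.73,-0.86,1.99,0.76,0.50,0.36,0.02,1.32
alcohol,0.59,1.01,-1.39,2.54,0.59,0.41,0.31,0.02,1.15
medicine_omitted,0.52,0.97,-1.38,2.42,0.54,0.37,0.28,0.01,1.04
irritability,0.05,0.74,-1.41,1.49,0.06,0.59,0.42,0.02,1.57
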