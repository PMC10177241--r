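subject,n,height_m,weight_kg,forelimb_m,forelimb_height,grip_weight,velocity_ms_mean,velocity_ms_sd,duty_pct_mean,duty_pct_sd,stance_s_mean,stance_s_sd,swing_s_mean,swing_s_sd,stride_hz_mean,stride_hz_sd,stride_m_mean,stride_m_sd,recovery_pct_mean,recovery_pct_sd,predicted_period_s,period_s_mean,period_s_sd,ml_m_mean,ml_m_sd,vertical_m_mean,vertical_m_sd
1,19,1.70,65.77,0.70,0.41,0.77,0.59,0.11,62.02,4.61,0.85,0.17,0.53,0.16,0.75,0.15,0.80,0.19,33.99,10.42,2.10,1.39,0.31,0.45,0.17,0.24,0.11
2,10,1.75,85.73,0.77,0.44,0.53,0.54,0.04,71.95,3.71,0.84,0.11,0.32,0.03,0.87,0.07,0.62,0.06,36.06,7.84,2.10,1.16,0.10,0.25,0.15,0.10,0.06
3,5,1.68,66.22,0.66,0.39,0.47,0.49,0.05,77.54,2.59,1.10,0.14,0.32,0.03,0.71,0.07,0.69,0.00,19.75,5.45,2.12,1.41,0.14,0.39,0.17,0.31,0.10
4,10,1.85,79.38,0.75,0.40,0.57,0.66,0.06,73.87,1.58,0.78,0.07,0.27,0.03,0.96,0.09,0.69,0.00,15.63,10.29,2.24,1.05,0.10,0.40,0.14,0.14,0.06
5,6,1.83,102.15,0.76,0.42,,0.44,0.05,81.72,2.19,1.22,0.14,0.27,0.02,0.67,0.06,0.66,0.05,29.21,10.74,2.30,1.49,0.13,0.39,0.18,0.38,0.22
6,5,1.75,74.39,0.74,0.42,0.42,0.50,0.04,79.72,2.27,1.10,0.10,0.28,0.01,0.73,0.05,0.69,0.00,28.39,5.31,2.16,1.38,0.10,0.37,0.12,0.23,0.15
7,7,1.75,80.20,0.71,0.41,0.64,0.68,0.06,72.10,2.50,0.74,0.09,0.28,0.01,0.98,0.09,0.69,0.00,30.07,6.55,2.22,1.03,0.09,0.10,0.08,0.17,0.09
8,8,1.93,100.24,0.85,0.44,0.36,0.49,0.08,76.36,3.64,0.97,0.11,0.30,0.05,0.79,0.07,0.62,0.08,28.08,9.43,2.40,1.27,0.12,0.40,0.13,0.27,0.12
9,10,1.79,97.52,0.76,0.43,0.61,0.70,0.06,66.10,3.13,0.62,0.06,0.32,0.03,1.07,0.07,0.65,0.03,37.07,11.08,2.24,0.94,0.06,0.13,0.05,0.13,0.07
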