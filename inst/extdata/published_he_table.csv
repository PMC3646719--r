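starting_age,sex,measure,estimate,lower,upper
45,female,total,28.04,25.71,33.49
45,female,active,11.72,10.43,13.77
45,female,moderate,10.90,9.44,13.39
45,female,severe,5.41,4.31,7.06
45,male,total,25.39,23.31,28.83
45,male,active,15.06,13.61,16.92
45,male,moderate,6.57,5.39,8.49
45,male,severe,3.76,2.78,5.36
55,female,total,20.97,19.19,31.72
55,female,active,6.50,5.44,9.50
55,female,moderate,9.21,8.04,14.48
55,female,severe,5.26,4.23,7.79
55,male,total,19.38,17.51,25.00
55,male,active,9.41,8.19,11.80
55,male,moderate,6.11,4.98,8.45
55,male,severe,3.86,2.81,5.46
65,female,total,14.85,13.46,21.61
65,female,active,3.21,2.45,4.34
65,female,moderate,6.58,5.49,9.84
65,female,severe,5.06,3.98,6.92
65,male,total,13.70,12.37,16.08
65,male,active,5.41,4.42,6.72
65,male,moderate,4.48,3.60,6.19
65,male,severe,3.82,2.76,5.40
75,female,total,8.85,8.20,15.14
75,female,active,1.69,1.05,2.99
75,female,moderate,3.78,2.89,7.24
75,female,severe,3.38,2.54,5.19
75,male,total,8.23,7.54,12.73
75,male,active,2.76,1.96,4.10
75,male,moderate,2.93,2.27,5.37
75,male,severe,2.54,1.83,3.72
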