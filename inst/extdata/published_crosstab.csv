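age_group,year,state,n,published_pct
45-64,2006,healthy,427,72.4
45-64,2006,moderate,132,22.4
45-64,2006,severe,31,5.3
45-64,2008,healthy,537,67.4
45-64,2008,moderate,200,25.1
45-64,2008,severe,41,5.1
45-64,2008,dead,19,2.4
45-64,2010,healthy,428,56.8
45-64,2010,moderate,239,31.7
45-64,2010,severe,64,8.5
45-64,2010,dead,23,3.1
65+,2006,healthy,34,54.0
65+,2006,moderate,20,31.7
65+,2006,severe,9,14.3
65+,2008,healthy,120,41.0
65+,2008,moderate,108,36.9
65+,2008,severe,62,21.2
65+,2008,dead,3,1.0
65+,2010,healthy,87,24.6
65+,2010,moderate,142,40.1
65+,2010,severe,93,26.3
65+,2010,dead,32,9.0
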