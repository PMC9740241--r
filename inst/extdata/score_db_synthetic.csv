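bos_score,fractured_6mo
2.6,TRUE
2.75,TRUE
2.9,TRUE
3.05,TRUE
3.2,TRUE
3.35,TRUE
3.5,TRUE
3.65,TRUE
3.8,TRUE
3.95,TRUE
4.1,TRUE
4.25,TRUE
4.4,TRUE
4.55,FALSE
4.7,FALSE
4.85,FALSE
5,FALSE
5.15,FALSE
5.3,FALSE
5.45,FALSE
5.6,FALSE
5.75,FALSE
5.9,FALSE
6.05,FALSE
6.2,FALSE
6.35,FALSE
6.5,FALSE
6.65,FALSE
6.8,FALSE
6.95,FALSE
7.1,FALSE
7.25,FALSE
7.4,FALSE
7.6,FALSE
7.73,FALSE
7.86,FALSE
7.99,FALSE
8.11,FALSE
8.24,FALSE
8.37,FALSE
8.5,FALSE
8.63,FALSE
8.76,FALSE
8.89,FALSE
9.01,FALSE
9.14,FALSE
9.27,FALSE
9.4,FALSE
9.53,FALSE
9.66,FALSE
9.79,FALSE
9.91,FALSE
10.04,FALSE
10.17,FALSE
10.3,FALSE
10.43,FALSE
10.56,FALSE
10.69,FALSE
10.81,FALSE
10.94,FALSE
11.07,FALSE
11.2,FALSE
11.33,FALSE
11.46,FALSE
11.59,FALSE
11.71,FALSE
11.84,FALSE
11.97,FALSE
12.1,FALSE
12.23,FALSE
12.36,FALSE
12.49,FALSE
12.61,FALSE
12.74,FALSE
12.87,FALSE
13,FALSE
13.13,FALSE
13.26,FALSE
13.39,FALSE
13.51,FALSE
13.64,FALSE
13.77,FALSE
13.9,FALSE
14.03,FALSE
14.16,FALSE
14.29,FALSE
14.41,FALSE
14.54,FALSE
14.67,FALSE
14.8,FALSE
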