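node_id,opinion,epsilon,label
u01,0.3344,0.239,Pro
u02,0.3185,0.277,Pro
u03,0.0923,0.272,Pro
u04,0.3174,0.334,Pro
u05,0.3514,0.239,Pro
u06,0.296,0.189,Pro
u07,0.3189,0.34,Pro
u08,0.365,0.188,Pro
u09,0.2888,0.286,Pro
u10,0.153,0.306,Pro
u11,0.1349,0.278,Pro
u12,0.396,0.219,Pro
u13,0.3531,0.3,Pro
u14,0.1899,0.233,Pro
u15,0.3995,0.291,Pro
u16,0.3137,0.295,Pro
u17,0.3928,0.322,Pro
u18,0.3578,0.204,Pro
u19,0.3176,0.318,Pro
u20,0.304,0.197,Pro
u21,0.8594,0.258,Against
u22,0.709,0.23,Against
u23,0.8426,0.272,Against
u24,0.86,0.22,Against
u25,0.859,0.259,Against
u26,0.8876,0.199,Against
u27,0.8203,0.169,Against
u28,0.9399,0.312,Against
u29,0.7402,0.162,Against
u30,0.9018,0.213,Against
u31,0.8035,0.212,Against
u32,0.9081,0.255,Against
u33,0.9357,0.209,Against
u34,0.9503,0.261,Against
u35,0.9145,0.348,Against
u36,0.7916,0.156,Against
u37,0.9238,0.159,Against
u38,0.8001,0.277,Against
u39,0.9397,0.329,Against
u40,0.8571,0.337,Against
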