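0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0138,0.2571,0.5263,0.7937,0.8927,0.9134,0.9322,0.9405,0.9471,0.9518,0.948,0.9433,0.9369,0.9235,0.9099,0.8929,0.8024,0.6264,0.4089,0.157,0.0017,0,0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0.0251,0.4154,0.7494,0.9598,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9993,0.904,0.7289,0.4844,0.1242,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0.0298,0.3988,0.9259,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9224,0.5235,0.1106,0,0,0
0,0,0,0,0,0,0.0345,0.5712,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.4,0,0,0
0,0,0,0,0,0.3486,0.9834,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.4,0,0,0
0,0,0,0.0013,0.678,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.4,0,0,0
0,0,0.0095,0.7388,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9612,0.887,0.8309,0.8024,0.7869,0.8007,0.8266,0.8628,0.9362,0.9957,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.4,0,0,0
0,0,0.6008,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9267,0.7027,0.2478,0.0031,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0031,0.2212,0.5537,0.8329,0.9455,1,1,1,1,1,1,1,0.4,0,0,0
0,0.2819,0.9998,1,1,1,1,1,1,1,1,1,1,1,0.6518,0.0234,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0117,0.0961,0.6499,1,1,1,1,0.4,0,0,0
0,0.8078,1,1,1,1,1,1,1,1,1,1,0.8475,0.0856,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.067,0.3766,0.928,0.4,0,0,0
0.1837,1,1,1,1,1,1,1,1,1,1,0.8358,0.0224,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.464,1,1,1,1,1,1,1,1,1,1,0.1947,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.6588,1,1,1,1,1,1,1,1,1,0.8314,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.7336,1,1,1,1,1,1,1,1,1,0.6806,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.7575,1,1,1,1,1,1,1,1,1,0.7107,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.6991,1,1,1,1,1,1,1,1,1,0.9506,0.0225,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.5443,1,1,1,1,1,1,1,1,1,1,0.5395,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.2937,1,1,1,1,1,1,1,1,1,1,1,0.5573,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0.0121,0.9169,1,1,1,1,1,1,1,1,1,1,1,0.9241,0.4005,0.0077,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0,0.4336,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.8507,0.3735,0.1104,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0,0,0.7773,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9747,0.5905,0.152,0.0436,0.0082,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0,0,0.0358,0.8781,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9959,0.9391,0.866,0.6061,0.2273,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0.0384,0.7573,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9396,0.7263,0.4576,0.1106,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0.3745,0.9598,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.8758,0.4174,0.1016,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0.4562,0.9612,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9948,0.4834,0.0409,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0.0042,0.1149,0.7446,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9969,0.8155,0.069,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0,0.1299,0.4116,0.8205,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.6817,0.0251,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0094,0.2141,0.4937,0.7161,0.9043,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9353,0.158,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.1318,0.5122,0.8319,0.9332,0.9959,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9951,0.1731,0,0
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0097,0.0529,0.3053,0.8647,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9567,0.0379,0
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.106,0.462,0.9613,1,1,1,1,1,1,1,1,1,1,1,1,1,0.6238,0
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.2464,0.9103,1,1,1,1,1,1,1,1,1,1,1,0.9956,0.1026
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0031,0.7792,1,1,1,1,1,1,1,1,1,1,1,0.4451
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0155,0.9398,1,1,1,1,1,1,1,1,1,1,0.6857
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.4822,1,1,1,1,1,1,1,1,1,1,0.8386
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.2384,1,1,1,1,1,1,1,1,1,1,0.8976
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.1767,1,1,1,1,1,1,1,1,1,1,0.8645
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.298,1,1,1,1,1,1,1,1,1,1,0.7804
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.6334,1,1,1,1,1,1,1,1,1,1,0.5605
0.6795,0.1886,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.2558,1,1,1,1,1,1,1,1,1,1,1,0.2452
1,1,0.9972,0.6315,0.1793,0.0066,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.2711,0.9958,1,1,1,1,1,1,1,1,1,1,0.8272,0
1,1,1,1,1,1,0.9266,0.3298,0.0231,0.002,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0378,0.7986,1,1,1,1,1,1,1,1,1,1,1,0.9991,0.2504,0
1,1,1,1,1,1,1,1,1,0.98,0.8702,0.6122,0.2212,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0329,0.491,0.8992,1,1,1,1,1,1,1,1,1,1,1,1,1,0.5031,0,0
1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9836,0.8559,0.7213,0.629,0.5329,0.4458,0.4074,0.3689,0.3613,0.3865,0.4447,0.5288,0.6359,0.7619,0.9284,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.5811,0,0,0
1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.995,0.4514,0,0,0,0
1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.924,0.1173,0,0,0,0,0
1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9753,0.2983,0.0041,0,0,0,0,0,0
0.2902,0.6071,0.9435,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.7953,0.249,0,0,0,0,0,0,0,0,0
0,0,0,0,0.0765,0.4091,0.6907,0.8652,0.9929,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0.9626,0.7455,0.32,0.0025,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0.019,0.2933,0.5987,0.8482,0.9169,0.9466,0.9744,0.9974,1,1,1,1,1,1,1,1,1,0.9998,0.9859,0.9539,0.9169,0.8381,0.4866,0.1018,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
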