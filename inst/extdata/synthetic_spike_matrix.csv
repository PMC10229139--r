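gene,cell0001,cell0002,cell0003,cell0004,cell0005,cell0006,cell0007,cell0008,cell0009,cell0010,cell0011,cell0012,cell0013,cell0014,cell0015,cell0016,cell0017,cell0018,cell0019,cell0020,cell0021,cell0022,cell0023,cell0024,cell0025,cell0026,cell0027,cell0028,cell0029,cell0030,cell0031,cell0032,cell0033,cell0034,cell0035,cell0036,cell0037,cell0038,cell0039,cell0040,cell0041,cell0042,cell0043,cell0044,cell0045,cell0046,cell0047,cell0048,cell0049,cell0050,cell0051,cell0052,cell0053,cell0054,cell0055,cell0056,cell0057,cell0058,cell0059,cell0060,cell0061,cell0062,cell0063,cell0064,cell0065,cell0066,cell0067,cell0068,cell0069,cell0070,cell0071,cell0072,cell0073,cell0074,cell0075,cell0076,cell0077,cell0078,cell0079,cell0080
SG1,2.942,1.265,2.453,3.49,1.997,2.68,3.404,2.917,2.234,0.904,4.95,1.928,2.598,4.19,3.6,5.234,4.585,1.181,3.204,2.196,2.809,3.784,2.587,2.972,3.618,2.663,1.462,2.89,2.232,2.136,4.885,3.481,2.854,4.81,1.719,2.938,4.17,4.632,3.949,3.326,5.036,2.531,1.986,3.581,2.101,3.559,3.406,2.717,2.439,3.02,3.303,3.42,2.792,3.245,1.629,0.706,2.428,2.997,1.886,4.123,2.842,3.012,2.917,3.577,3.835,1.675,1.564,3.19,1.844,3.636,3.993,3.636,3.272,2.677,3.194,4.836,3.129,1.608,3.145,3.795
SG2,2.736,2.178,1.743,0.906,3.548,3.874,4.358,3.354,1.269,2.143,4.001,4.472,2.949,3.324,2.206,2.454,2.522,4.769,2.738,5.314,1.997,2.831,0.545,3.63,4.137,3.633,3.03,2.795,2.57,3.391,3.78,1.784,2.934,3.852,4.838,3.122,2.031,4.494,1.284,2.029,2.364,2.195,2.839,3.836,3.501,2.386,2.014,3.054,3.227,2.731,3.259,3.35,4.477,3.315,3.014,3.217,3.79,4.742,2.279,3.929,3.331,1.123,1.952,4.217,2.51,4.104,1.972,1.713,2.743,2.115,3.46,3.327,2.057,3.98,1.275,2.578,3.514,3.214,4.086,3.796
SG3,3.727,2.398,3.638,3.16,3.427,2.083,1.114,3.123,3.657,3.749,3.106,2.19,2.703,3.515,4.436,1.387,2.335,2.938,3.424,2.432,3.935,3.135,4.109,2.574,1.845,3.402,3.575,3.93,4.074,2.735,3.153,3.054,3.416,1.799,1.511,3.573,2.822,3.306,2.815,3.044,4.228,2.757,4.332,0,4.194,4.071,1.924,1.772,3.2,1.734,1.929,1.491,1.422,3.878,5.094,3.762,3.834,2.89,5.677,4.596,2.219,2.119,2.917,1.684,2.932,2.544,2.614,3.534,4.235,2.173,2.593,3.48,2.427,4.083,1.432,2.564,4.581,2.854,3.536,2.493
SG4,2.41,3.8,2.3,3.201,2.394,3.815,5.034,2.639,1.941,2.224,3.128,3.949,3.59,2.038,1.382,5.011,4.052,2.465,2.24,3.156,2.482,2.998,1.846,3.269,3.794,2.743,3.014,2.52,2.489,3.278,2.947,3.62,2.586,4.042,4.665,2.416,3.358,2.779,3.17,3.036,1.954,3.42,1.534,5.608,1.879,2.244,3.785,4.27,2.586,3.951,4.255,4.482,4.441,2.362,1.226,2.053,1.547,3.399,0.354,1.648,3.406,4.007,3.315,4.363,3.168,3.565,2.505,2.417,1.872,3.54,3.767,2.488,3.307,1.877,4.557,3.8,1.314,3.192,1.92,2.947
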