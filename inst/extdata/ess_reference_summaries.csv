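scenario,trial,dose,mean,sd,ess,a,b
divergent,T1,0.1,0.027,0.031,26.3,0.7,25.6
divergent,T1,0.5,0.045,0.042,23.4,1.1,22.3
divergent,T1,1,0.058,0.048,22.7,1.3,21.4
divergent,T1,5,0.107,0.068,19.7,2.1,17.6
divergent,T1,10,0.144,0.079,18.8,2.7,16.1
divergent,T1,20,0.199,0.105,13.5,2.7,10.8
divergent,T2,0.1,0.070,0.110,4.3,0.3,4.0
divergent,T2,0.5,0.114,0.141,4.1,0.5,3.6
divergent,T2,1,0.143,0.158,4.0,0.6,3.4
divergent,T2,5,0.271,0.222,3.0,0.8,2.2
divergent,T2,10,0.357,0.260,2.4,0.9,1.5
divergent,T2,20,0.434,0.280,2.1,0.9,1.2
consistent,T1,0.1,0.046,0.043,23.0,1.1,21.9
consistent,T1,0.5,0.090,0.058,23.4,2.1,21.3
consistent,T1,1,0.126,0.064,25.8,3.3,22.5
consistent,T1,5,0.316,0.156,8.0,2.5,5.5
consistent,T1,10,0.420,0.210,4.7,2.0,2.7
consistent,T1,20,0.510,0.233,3.7,1.9,1.8
consistent,T2,0.1,0.073,0.111,4.5,0.3,4.2
consistent,T2,0.5,0.121,0.138,4.6,0.6,4.0
consistent,T2,1,0.154,0.153,4.6,0.7,3.9
consistent,T2,5,0.298,0.206,4.0,1.2,2.8
consistent,T2,10,0.395,0.242,3.1,1.2,1.9
consistent,T2,20,0.483,0.259,2.7,1.3,1.4
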