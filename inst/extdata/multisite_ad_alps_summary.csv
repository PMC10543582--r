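group,scanner,feature,stage,mean,sd
CN,DiscoveryMR750,alps_left,before,1.55,0.25
CN,DiscoveryMR750,alps_left,after,1.55,0.22
CN,DiscoveryMR750,alps_right,before,1.51,0.21
CN,DiscoveryMR750,alps_right,after,1.52,0.19
CN,SignaHDxt,alps_left,before,1.50,0.18
CN,SignaHDxt,alps_left,after,1.56,0.24
CN,SignaHDxt,alps_right,before,1.48,0.15
CN,SignaHDxt,alps_right,after,1.54,0.19
CN,PrismaFit,alps_left,before,1.63,0.27
CN,PrismaFit,alps_left,after,1.52,0.23
CN,PrismaFit,alps_right,before,1.68,0.26
CN,PrismaFit,alps_right,after,1.53,0.21
AD,DiscoveryMR750,alps_left,before,1.50,0.32
AD,DiscoveryMR750,alps_left,after,1.50,0.28
AD,DiscoveryMR750,alps_right,before,1.43,0.22
AD,DiscoveryMR750,alps_right,after,1.45,0.20
AD,SignaHDxt,alps_left,before,1.34,0.14
AD,SignaHDxt,alps_left,after,1.37,0.19
AD,SignaHDxt,alps_right,before,1.37,0.15
AD,SignaHDxt,alps_right,after,1.41,0.20
AD,PrismaFit,alps_left,before,1.49,0.19
AD,PrismaFit,alps_left,after,1.39,0.17
AD,PrismaFit,alps_right,before,1.56,0.28
AD,PrismaFit,alps_right,after,1.43,0.22
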