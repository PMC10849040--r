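"lambda","method","k_tot","k_forward","k_backward","k_stderr","sigma_z_eq","fit_rms"
2,"forster",0.360266548675431,0.222526989387927,0.137739559287504,NA,-0.235346385647392,NA
2,"redfield",0.259693506065594,0.160586881049355,0.0991066250162395,NA,-0.236741599605445,0.0355365560300337
2,"mash_cap",0.27059033065314,0.167005699687434,0.103584630965706,0.00492222050685606,-0.234380395517624,0.0469814315151616
20,"forster",2.12934171885065,1.31529576537966,0.814045953470989,NA,-0.235401301477919,NA
20,"redfield",1.30891849783648,0.81144707855092,0.497471419285565,NA,-0.239874109644203,0.00280705693055215
20,"mash_cap",1.77355506672818,1.09450061480634,0.67905445192184,0.0295969656213828,-0.234244862580392,0.0103166573428095
100,"forster",1.05458788671034,0.651412520525292,0.403175366185049,NA,-0.235387830135797,NA
100,"redfield",1.2819117941266,0.795210353342436,0.486701440784163,NA,-0.240663136084545,0.00124639715809263
100,"mash_cap",0.955042856932082,0.589380158992265,0.365662697939816,0.0218207667186899,-0.234248609293937,0.00807207377598065
500,"forster",0.193091655410049,0.119270964323449,0.0738206910866004,NA,-0.235381861221968,NA
500,"redfield",1.24988725809846,0.775461403445183,0.474425854653282,NA,-0.240850162157734,0.000122679839608436
500,"mash_cap",0.17200186278791,0.107026926550248,0.0649749362376624,0.0036397812688495,-0.244485667951388,0.0174411143582761
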