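[{"lambda":2,"method":"forster","k_tot":0.360266548675431,"k_forward":0.222526989387927,"k_backward":0.137739559287504,"sigma_z_eq":-0.235346385647392},{"lambda":2,"method":"redfield","k_tot":0.259693506065594,"k_forward":0.160586881049355,"k_backward":0.0991066250162395,"sigma_z_eq":-0.236741599605445,"fit_rms":0.0355365560300337},{"lambda":2,"method":"mash_cap","k_tot":0.27059033065314,"k_forward":0.167005699687434,"k_backward":0.103584630965706,"k_stderr":0.00492222050685606,"sigma_z_eq":-0.234380395517624,"fit_rms":0.0469814315151616},{"lambda":20,"method":"forster","k_tot":2.12934171885065,"k_forward":1.31529576537966,"k_backward":0.814045953470989,"sigma_z_eq":-0.235401301477919},{"lambda":20,"method":"redfield","k_tot":1.30891849783648,"k_forward":0.81144707855092,"k_backward":0.497471419285565,"sigma_z_eq":-0.239874109644203,"fit_rms":0.00280705693055215},{"lambda":20,"method":"mash_cap","k_tot":1.77355506672818,"k_forward":1.09450061480634,"k_backward":0.67905445192184,"k_stderr":0.0295969656213828,"sigma_z_eq":-0.234244862580392,"fit_rms":0.0103166573428095},{"lambda":100,"method":"forster","k_tot":1.05458788671034,"k_forward":0.651412520525292,"k_backward":0.403175366185049,"sigma_z_eq":-0.235387830135797},{"lambda":100,"method":"redfield","k_tot":1.2819117941266,"k_forward":0.795210353342436,"k_backward":0.486701440784163,"sigma_z_eq":-0.240663136084545,"fit_rms":0.00124639715809263},{"lambda":100,"method":"mash_cap","k_tot":0.955042856932082,"k_forward":0.589380158992265,"k_backward":0.365662697939816,"k_stderr":0.0218207667186899,"sigma_z_eq":-0.234248609293937,"fit_rms":0.00807207377598065},{"lambda":500,"method":"forster","k_tot":0.193091655410049,"k_forward":0.119270964323449,"k_backward":0.0738206910866004,"sigma_z_eq":-0.235381861221968},{"lambda":500,"method":"redfield","k_tot":1.24988725809846,"k_forward":0.775461403445183,"k_backward":0.474425854653282,"sigma_z_eq":-0.240850162157734,"fit_rms":0.000122679839608436},{"lambda":500,"method":"mash_cap","k_tot":0.17200186278791,"k_forward":0.107026926550248,"k_backward":0.0649749362376624,"k_stderr":0.0036397812688495,"sigma_z_eq":-0.244485667951388,"fit_rms":0.0174411143582761}]
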