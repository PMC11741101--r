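polymorph,simulation,n_tot_s,n_tot,n_ss,temperature
beta,1,11974,136,75,298
beta,2,15869,197,120,298
beta,3,16774,245,169,298
beta,4,19348,316,238,298
beta,5,11879,151,78,298
beta,6,15717,214,127,298
beta,7,16648,263,183,298
beta,8,19190,336,242,298
alpha,1,13769,292,114,298
alpha,2,15139,360,177,298
alpha,3,16841,428,242,298
alpha,4,13621,310,132,298
alpha,5,15038,371,176,298
alpha,6,16841,428,239,298
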