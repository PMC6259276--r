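# Published summary statistics of the CoMFA and CoMSIA models of the
# dibenzazepine/dibenzoxazepine TRPA1 agonist series (internal PLS diagnostics
# and external test-set validation), used as reference inputs for derived
# quantities such as rm^2.
model,statistic,value
comfa,r2cv,0.631
comfa,r2,0.986
comfa,onc,6
comfa,see,0.154
comfa,f,160.559
comfa,contrib_steric,0.541
comfa,contrib_electrostatic,0.459
comfa,r2pred,0.967
comfa,k,0.984
comfa,r0sq,0.984
comfa,rm2,0.942
comfa,ratio,0.002
comsia,r2cv,0.542
comsia,r2,0.981
comsia,onc,6
comsia,see,0.180
comsia,f,117.466
comsia,contrib_steric,0.146
comsia,contrib_electrostatic,0.403
comsia,contrib_hydrophobic,0.160
comsia,contrib_donor,0.075
comsia,contrib_acceptor,0.215
comsia,r2pred,0.981
comsia,k,0.988
comsia,r0sq,0.988
comsia,rm2,0.899
comsia,ratio,-0.007
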