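scale,amino_acid,value
asa,A,115
asa,C,135
asa,D,150
asa,E,190
asa,F,210
asa,G,75
asa,H,195
asa,I,175
asa,K,200
asa,L,170
asa,M,185
asa,N,160
asa,P,145
asa,Q,180
asa,R,225
asa,S,115
asa,T,140
asa,V,155
asa,W,255
asa,Y,230
asa_folded,A,31.5
asa_folded,C,13.9
asa_folded,D,60.9
asa_folded,E,72.3
asa_folded,F,28.7
asa_folded,G,25.2
asa_folded,H,46.7
asa_folded,I,23
asa_folded,K,110.3
asa_folded,L,29
asa_folded,M,30.5
asa_folded,N,62.2
asa_folded,P,53.7
asa_folded,Q,74
asa_folded,R,93.8
asa_folded,S,44.2
asa_folded,T,46
asa_folded,V,23.5
asa_folded,W,41.7
asa_folded,Y,59.1
flexibility,A,0.357
flexibility,C,0.346
flexibility,D,0.511
flexibility,E,0.497
flexibility,F,0.314
flexibility,G,0.544
flexibility,H,0.323
flexibility,I,0.462
flexibility,K,0.466
flexibility,L,0.365
flexibility,M,0.295
flexibility,N,0.463
flexibility,P,0.509
flexibility,Q,0.493
flexibility,R,0.529
flexibility,S,0.507
flexibility,T,0.444
flexibility,V,0.386
flexibility,W,0.305
flexibility,Y,0.42
hydropathy,A,1.8
hydropathy,C,2.5
hydropathy,D,-3.5
hydropathy,E,-3.5
hydropathy,F,2.8
hydropathy,G,-0.4
hydropathy,H,-3.2
hydropathy,I,4.5
hydropathy,K,-3.9
hydropathy,L,3.8
hydropathy,M,1.9
hydropathy,N,-3.5
hydropathy,P,-1.6
hydropathy,Q,-3.5
hydropathy,R,-4.5
hydropathy,S,-0.8
hydropathy,T,-0.7
hydropathy,V,4.2
hydropathy,W,-0.9
hydropathy,Y,-1.3
hydrophilicity,A,-0.5
hydrophilicity,C,-1
hydrophilicity,D,3
hydrophilicity,E,3
hydrophilicity,F,-2.5
hydrophilicity,G,0
hydrophilicity,H,-0.5
hydrophilicity,I,-1.8
hydrophilicity,K,3
hydrophilicity,L,-1.8
hydrophilicity,M,-1.3
hydrophilicity,N,0.2
hydrophilicity,P,0
hydrophilicity,Q,0.2
hydrophilicity,R,3
hydrophilicity,S,0.3
hydrophilicity,T,-0.4
hydrophilicity,V,-1.5
hydrophilicity,W,-3.4
hydrophilicity,Y,-2.3
pk_side_chain,A,0
pk_side_chain,C,8.3
pk_side_chain,D,3.65
pk_side_chain,E,4.25
pk_side_chain,F,0
pk_side_chain,G,0
pk_side_chain,H,6
pk_side_chain,I,0
pk_side_chain,K,10.53
pk_side_chain,L,0
pk_side_chain,M,0
pk_side_chain,N,0
pk_side_chain,P,0
pk_side_chain,Q,0
pk_side_chain,R,12.48
pk_side_chain,S,0
pk_side_chain,T,0
pk_side_chain,V,0
pk_side_chain,W,0
pk_side_chain,Y,10.07
polarity,A,8.1
polarity,C,5.5
polarity,D,13
polarity,E,12.3
polarity,F,5.2
polarity,G,9
polarity,H,10.4
polarity,I,5.2
polarity,K,11.3
polarity,L,4.9
polarity,M,5.7
polarity,N,11.6
polarity,P,8
polarity,Q,10.5
polarity,R,10.5
polarity,S,9.2
polarity,T,8.6
polarity,V,5.9
polarity,W,5.4
polarity,Y,6.2
solvent_exposed_area,A,113
solvent_exposed_area,C,140
solvent_exposed_area,D,151
solvent_exposed_area,E,183
solvent_exposed_area,F,218
solvent_exposed_area,G,85
solvent_exposed_area,H,194
solvent_exposed_area,I,182
solvent_exposed_area,K,211
solvent_exposed_area,L,180
solvent_exposed_area,M,204
solvent_exposed_area,N,158
solvent_exposed_area,P,143
solvent_exposed_area,Q,189
solvent_exposed_area,R,241
solvent_exposed_area,S,122
solvent_exposed_area,T,146
solvent_exposed_area,V,160
solvent_exposed_area,W,259
solvent_exposed_area,Y,229
volume,A,88.6
volume,C,108.5
volume,D,111.1
volume,E,138.4
volume,F,189.9
volume,G,60.1
volume,H,153.2
volume,I,166.7
volume,K,168.6
volume,L,166.7
volume,M,162.9
volume,N,114.1
volume,P,112.7
volume,Q,143.8
volume,R,173.4
volume,S,89
volume,T,116.1
volume,V,140
volume,W,227.8
volume,Y,193.6
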