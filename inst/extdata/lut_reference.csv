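"musp","sigma","bvf","b","dR","dG","dB","WLL","PEL","co_r","co_g","co_b","cross_r","cross_g","cross_b","seed"
20,0.5,0.006,1.93149331767988,0.987910464949351,1.06270963858645,0.877979224285925,84.7705484048795,2.92859932782172,16.8576303932222,15.3142975879546,11.6776458851739,15.8697199282728,14.2515879493681,10.799666660888,424242
20,1,0.006,1.86513595296546,1.00399587986997,0.925961079049745,0.751214796047863,84.8817164024286,2.68117175496758,16.9109050801944,15.2600447425769,11.6104942559268,15.9069092003245,14.3340836635271,10.8592794598789,424242
20,2,0.006,1.77822056259612,0.860185123770869,0.79141423569348,0.692749114248706,85.3465025382991,2.34434847371305,16.9590441771817,15.3035653130679,11.5828160157565,16.0988590534109,14.5121510773744,10.8900669015077,424242
20,4,0.006,1.65692263582814,0.783800330765782,0.776717152036042,0.642889197791591,85.1492862804892,2.20340668059342,16.9032979024797,15.2316896366012,11.5413589414605,16.1194975717139,14.4549724845651,10.8984697436689,424242
20,6,0.006,1.56154814253738,0.749522808030708,0.665449131439289,0.610183205325701,85.1480073916083,2.0251551447957,16.9172980024926,15.150093105813,11.5191901598965,16.1677751944619,14.4846439743737,10.9090069545708,424242
20,8,0.006,1.47839625435592,0.77882512092869,0.713683425332306,0.602766050473443,85.2341689559705,2.09527459673444,16.9286084520159,15.1833669851953,11.5527463391413,16.1497833310872,14.469683559863,10.9499802886679,424242
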