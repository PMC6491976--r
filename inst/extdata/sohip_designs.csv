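name,C,T,m,D,X
sohip_proposed,6,6,8,3,000112000112001122001122011222011222
sohip_optimal_w0,6,6,8,3,000001000011000112011222112222122222
sohip_optimal_w05,6,5,4,3,001110011111122112222222222222
allarms_d_optimal_w0,6,6,8,3,000012000012000122001222012222012222
allarms_d_optimal_w05,6,6,5,3,000012000012001122011222012222012222
fourarm_proposed,6,8,8,4,000112230001122300112233001122330112233301122333
fourarm_d_optimal,6,8,8,4,000000110000112300122333011112221222333322333333
fourarm_a_optimal,6,8,8,4,000000110000113300111222111122221122233322233333
fourarm_e_optimal,6,8,8,4,000000130000112200011333111122221122333322333333
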