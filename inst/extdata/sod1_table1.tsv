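label	hgvs_c	hgvs_p	ptc_printed	reported_class
V120Qfs8	c.358-304C>G	p.Val120Glnfs*8	127	splicing
L127X	c.380 T > A	p.Leu127*	127	nonsense
K137X	c.409A>T	p.Lys137*	137	nonsense
G142X	c.424G>T	p.Gly142*	142	nonsense
C147X	c.441 T > A	p.Cys147*	147	nonsense
V30Dfs8	c.88_89insA	p.Val30Aspfs*8	37	frameshift
K92Rfs9	c.275_276delAA	p.Lys92Argfs*9	100	frameshift
S108Lfs15	c.320dupT	p.Ser108Leufs*15	122	frameshift
C112Wfs11	c.335dupG	p.Cys112Trpfs*11	122	frameshift
V119Kfs5	c.355delGinsAAAAC	p.Val119Lysfs*5	123	frameshift
L127Gfs6	c.379_380delTT	p.Leu127Glyfs*6	132	frameshift
K129Gfs6	c.380_383dupTGGG	p.Lys129Glyfs*6	134	frameshift
E134Dfs2	c.401_402insTT	p.Glu134Aspfs*2	135	frameshift
N132Qfs5	c.383_392dupGCAAAGGTGG	p.Asn132Glnfs*5	136	frameshift
L145Ffs3	c.435delGinsCGTTTA	p.Leu145Phefs*3	147	frameshift
D126Tfs24	c.376delG	p.Asp126Thrfs*24	149	frameshift
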