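code,points
H200,10
H201,9
H202,8
H203,8
H204,6
H205,9
H220,6
H221,5
H222,7
H223,5
H224,7
H225,6
H226,4
H228,4
H240,9
H241,8
H242,6
H250,7
H251,5
H252,4
H260,7
H261,5
H270,5
H271,8
H272,5
H280,2
H281,2
H290,3
H300,10
H301,8
H302,4
H304,6
H310,10
H311,8
H312,4
H314,7
H315,2
H317,4
H318,6
H319,2
H330,10
H331,8
H332,4
H334,6
H335,3
H336,3
H340,10
H341,7
H350,10
H351,7
H360,10
H361,7
H362,6
H370,9
H371,6
H372,8
H373,5
H400,6
H410,8
H411,6
H412,4
H413,2
H420,6
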