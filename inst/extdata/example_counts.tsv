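# n = 200
# N = 10000
category_id	t	s
GO:1	12	40
GO:2	1	50
GO:3	0	60
GO:4	9	60
GO:5	2	45
GO:6	1	55
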