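sample_id	tA	tB	tC	tD
s1	1000	400	60	40
s2	500	300	50	50
s3	1199	700	40	61
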