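state	category
1	active
2	active
3	active
4	active
5	active
6	active
7	active
8	neutral
9	quiescent
10	neutral
11	neutral
12	neutral
13	neutral
14	neutral
15	quiescent
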