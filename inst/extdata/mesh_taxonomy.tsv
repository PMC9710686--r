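D006801	9606
D051379	10090
D051381	10116
D004331	7227
D017173	6239
D012441	4932
D015687	7955
D004926	562
D014983	8355
D017360	3702
D011817	9986
D017930	9031
D002522	9685
D004285	9615
D030541	9598
D008822	9544
D011916	10116
D014343	10029
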