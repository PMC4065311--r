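sequence	ratio_study1	ratio_study2	in_predictive_lupus	in_diagnostic_lupus	in_predictive_behavior
AGAFRERRYKPMMWLHVGSC	2.36	3.24	FALSE	FALSE	FALSE
AGVRHKFHPYLMQFRRHGSC	2.48	2.44	FALSE	FALSE	FALSE
AQLGMYGVYRPVEIWPDGSC	3.25	2.58	FALSE	TRUE	TRUE
DDTLYNAHKHLKWFGFIGSC	2.71	3.21	FALSE	TRUE	FALSE
EKFKRPRWPHLPFTHWDGSC	2.66	2.46	FALSE	FALSE	FALSE
EPKLWFKPRRGGYRHRHGSC	2.87	3.02	FALSE	TRUE	FALSE
EPSLQVITEYNINFLTIGSC	2.4	3.03	FALSE	FALSE	TRUE
EQEDYDDDEEQEQDEDDGSC	2.37	2.36	FALSE	FALSE	FALSE
ERNRRESDSKERKNYDHGSC	3.25	2.65	FALSE	FALSE	FALSE
FPGDRRSGRAFPEVRWRGSC	3.27	2.76	FALSE	TRUE	FALSE
GFHGPGMLGKTGRLSYGGSC	2.72	2.49	FALSE	FALSE	FALSE
GLVSRIPSVPKHDEWTFGSC	2.45	2.49	FALSE	TRUE	FALSE
GRVPQDFNTPSFDRVFWGSC	2.72	2.89	FALSE	TRUE	FALSE
GWLKAMGPFPWGRLVQNGSC	2.93	3.1	FALSE	TRUE	TRUE
IGQRLKGKDENIRFENFGSC	2.4	4.23	FALSE	TRUE	TRUE
ILDRRETAWNEHFSKFRGSC	3.37	3.22	FALSE	TRUE	FALSE
IPDGWLKNVYRVRVPWPGSC	2.64	2.34	FALSE	FALSE	FALSE
IRFVAILVFVIIILIARGSC	2.34	2.95	FALSE	FALSE	FALSE
KLLMTDFMAKWPRNGWYGSC	3.78	2.72	FALSE	TRUE	FALSE
KTHHSMWKGRITHELFAGSC	2.45	2.52	FALSE	FALSE	TRUE
KVDYVNQWARRRIFMAPGSC	3.27	3.35	FALSE	TRUE	FALSE
LAFAWKPDPWQSLVTKFGSC	3.49	2.72	FALSE	FALSE	FALSE
PMLFWKWHRQLNQQGRRGSC	3.13	2.44	FALSE	TRUE	FALSE
PSAWEWIPRNQHLNKFRGSC	3.38	2.76	FALSE	TRUE	TRUE
PYRFDWAALPLKKPMWRGSC	2.57	3.16	FALSE	TRUE	FALSE
QKKPPDYRTWHHPFYNGGSC	3.04	3.01	FALSE	TRUE	FALSE
QKRWLQLPRNLMWRRETGSC	2.92	2.77	FALSE	TRUE	FALSE
QRVPIVKWLLWEPRALPGSC	2.99	2.48	FALSE	FALSE	FALSE
QSAYHNHRMKWRKIGIEGSC	2.47	3.21	FALSE	FALSE	FALSE
QSHWFYDRTKDVYPGRHGSC	4.79	2.64	FALSE	TRUE	FALSE
RAAMHESLKNWRVYREWGSC	2.49	2.91	FALSE	TRUE	TRUE
SRQGLHYNLDGLKPIFPGSC	2.77	3.34	FALSE	TRUE	FALSE
SSELDFRKYSFYVHRPDGSC	2.74	2.54	FALSE	FALSE	FALSE
TLNKRRSWRDGFTADEYGSC	2.31	2.39	FALSE	FALSE	FALSE
VDARMETFYDMQYPYYLGSC	2.37	2.46	FALSE	FALSE	FALSE
WKPIWHSFHKRRPQILNGSC	3.05	2.71	FALSE	TRUE	FALSE
WRTKAAMKWQKYQREHRGSC	2.6	2.62	FALSE	FALSE	FALSE
WSYKYKKKQAWDWPWDPGSC	2.93	2.74	FALSE	TRUE	FALSE
YYNVQQVDRWVKLQWGLGSC	2.67	2.7	FALSE	TRUE	FALSE
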