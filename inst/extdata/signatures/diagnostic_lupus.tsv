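sequence	ratio_study1	ratio_study2	in_predictive_lupus	in_diagnostic_behavior	in_predictive_behavior
ADGSNWAARHWIPRMPRGSC	3.404555813	2.332923454	FALSE	FALSE	FALSE
AMSFHRGWDRKYRMSNIGSC	2.599608572	2.484332734	FALSE	FALSE	TRUE
AQLGMYGVYRPVEIWPDGSC	2.872747926	2.519910261	FALSE	TRUE	TRUE
ATDKTRFHFLYDYIRSNGSC	2.399571763	2.880058556	FALSE	FALSE	FALSE
DDTLYNAHKHLKWFGFIGSC	2.515491313	3.037141329	FALSE	TRUE	FALSE
EATGNDWVITRGGMRRYGSC	2.556966833	3.171502541	FALSE	FALSE	FALSE
EMNNGRFHRWAQQERHPGSC	2.880990297	2.507493739	FALSE	FALSE	FALSE
EMSWPRKPWRSKYYHEIGSC	2.353443025	2.435039315	TRUE	FALSE	TRUE
ENILPTGRDRVAGWYRYGSC	2.825255829	2.675812354	TRUE	FALSE	FALSE
EPKLWFKPRRGGYRHRHGSC	2.679076813	2.434485702	FALSE	TRUE	FALSE
ERIYRDHFIHEHKANIIGSC	2.389911067	2.665777953	FALSE	FALSE	TRUE
EWYYDPRGGTGSFYMRTGSC	2.826268307	3.144085944	FALSE	FALSE	TRUE
FNRDHREFFEHFGFDEPGSC	4.422628739	2.314403551	TRUE	FALSE	FALSE
FPGDRRSGRAFPEVRWRGSC	2.66924554	2.635674506	FALSE	TRUE	FALSE
FTLMTGKKMIVWDWQRDGSC	2.564037604	2.381362551	FALSE	FALSE	TRUE
FWEHHVFHSSRRDGWASGSC	2.951177541	2.464272834	FALSE	FALSE	FALSE
GLVSRIPSVPKHDEWTFGSC	2.38601487	2.329539073	FALSE	TRUE	FALSE
GRVPQDFNTPSFDRVFWGSC	2.513399666	2.788409089	FALSE	TRUE	FALSE
GWLKAMGPFPWGRLVQNGSC	2.681235945	3.008923213	FALSE	TRUE	TRUE
IEAMGPSQRYRGRYELIGSC	2.377783579	2.371993113	FALSE	FALSE	FALSE
IGQRLKGKDENIRFENFGSC	2.347244686	3.594919118	FALSE	TRUE	TRUE
ILDRRETAWNEHFSKFRGSC	2.781744911	2.979425643	FALSE	TRUE	FALSE
KAMSIHQLANPFDWHFWGSC	2.316559723	2.705671849	FALSE	FALSE	FALSE
KGYSIRHTEHAWPDIYVGSC	2.579657821	3.104342319	FALSE	FALSE	TRUE
KLLMTDFMAKWPRNGWYGSC	3.325866727	2.467180958	FALSE	TRUE	TRUE
KQHPIYIAHFLGTIVKRGSC	2.850248411	2.447758339	FALSE	FALSE	FALSE
KVDYVNQWARRRIFMAPGSC	2.933406801	2.826782754	FALSE	TRUE	FALSE
KWLQTQLNSAMYYIRLYGSC	3.442674101	2.816729922	FALSE	FALSE	FALSE
LAFAWKPDPWQSLVTKFGSC	3.276131888	2.698697705	FALSE	TRUE	FALSE
LFSFKEPQPFMWNKWQQGSC	3.390564552	2.759114763	FALSE	FALSE	FALSE
LRKISRGIWGMREAGEFGSC	2.476731381	3.603591875	FALSE	FALSE	FALSE
MFARAHNFDWVKWPLNRGSC	2.705759435	2.921507814	FALSE	FALSE	TRUE
MWMSWGWAMLWLNGMMQGSC	4.177408974	2.432118292	FALSE	FALSE	FALSE
PLVHPWYPTYIPGRHNMGSC	3.630154471	2.495553997	FALSE	FALSE	TRUE
PMLFWKWHRQLNQQGRRGSC	2.75721307	2.335852256	FALSE	TRUE	TRUE
PNPEAWARSFKRWNRKFGSC	3.313709957	3.508821684	FALSE	FALSE	TRUE
PSAWEWIPRNQHLNKFRGSC	3.112407959	2.391409291	FALSE	TRUE	TRUE
PTWRLPPYTDPPKYWHPGSC	4.201093721	3.373945327	FALSE	FALSE	FALSE
PYRFDWAALPLKKPMWRGSC	2.40624731	2.565057719	FALSE	TRUE	FALSE
QKKPPDYRTWHHPFYNGGSC	2.604969331	2.754487673	FALSE	TRUE	FALSE
QKRWLQLPRNLMWRRETGSC	2.664022568	2.529899901	FALSE	TRUE	FALSE
QRKIFFNYKLHKIWFTAGSC	2.362843141	2.462441712	FALSE	FALSE	FALSE
QSHWFYDRTKDVYPGRHGSC	3.992759382	2.329563875	FALSE	TRUE	FALSE
RAAMHESLKNWRVYREWGSC	2.388166554	2.725739509	FALSE	TRUE	TRUE
RPAFDKFADSYWYPPNLGSC	2.471919459	2.483799875	FALSE	FALSE	FALSE
RRLTKGIIRQYESQLWDGSC	2.38838007	3.049171397	FALSE	FALSE	FALSE
RTIYRWSQGALSWYMDAGSC	2.443171562	2.802208961	FALSE	FALSE	TRUE
SDQVIRGFKDVWQYKWFGSC	3.018394899	2.579167723	FALSE	FALSE	FALSE
SRDAGLQYPYHRWLTGWGSC	2.452812911	2.732221588	FALSE	FALSE	FALSE
SRLEQQHFATIPQIWYTGSC	2.462810107	2.571973953	FALSE	FALSE	FALSE
SRQGLHYNLDGLKPIFPGSC	2.652106822	2.808739776	FALSE	TRUE	FALSE
TLQRTWRRPLLEDLPWWGSC	5.695014524	3.855075257	FALSE	FALSE	FALSE
VQERMHNRTWKRFGGSMGSC	2.754519694	2.496803929	FALSE	FALSE	TRUE
WKPIWHSFHKRRPQILNGSC	2.50380818	2.372369774	FALSE	TRUE	TRUE
WNGPEWKYSEKSKRILFGSC	2.445136421	2.433467124	FALSE	FALSE	TRUE
WSYKYKKKQAWDWPWDPGSC	2.443311505	2.436968425	FALSE	TRUE	FALSE
WTWPSIRFVKGEEYGRFGSC	2.991053751	2.626530982	FALSE	FALSE	FALSE
YYNVQQVDRWVKLQWGLGSC	2.441114219	2.553038205	FALSE	TRUE	FALSE
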