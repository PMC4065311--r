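sequence	ratio_study1	ratio_study2	in_predictive_behavior	in_diagnostic_behavior	in_diagnostic_lupus
DKFHYWMYMLYGINDKIGSC	2.12	2.34	FALSE	FALSE	FALSE
DKLWKQIWTERHFMSHKGSC	1.57	4.3	TRUE	FALSE	FALSE
DWDSRQINPHIIHHVGRGSC	1.41	2.78	FALSE	FALSE	FALSE
EEHAHNKLFWWHRSRALGSC	1.61	2.52	FALSE	FALSE	FALSE
EMSWPRKPWRSKYYHEIGSC	1.46	3.36	TRUE	FALSE	TRUE
ENILPTGRDRVAGWYRYGSC	1.51	3.1	FALSE	FALSE	TRUE
FNRDHREFFEHFGFDEPGSC	1.4	3.61	FALSE	FALSE	TRUE
GYNYWIVEWDQDQWLMNGSC	1.39	2.76	FALSE	FALSE	FALSE
HWKRRHKHKWPKRHPHKGSC	1.92	2.64	FALSE	FALSE	FALSE
KIWAMRKPRYQYWNQPAGSC	1.41	2.86	FALSE	FALSE	TRUE
KWDHGQNGLFPPMHYIPGSC	1.54	3.07	FALSE	FALSE	FALSE
LEAHYKRSMHAQNWWEAGSC	1.41	2.6	FALSE	FALSE	FALSE
QYLWWQMLKIEWNSTYAGSC	6.22	2.61	FALSE	FALSE	FALSE
RHWYQDGSPLLAPVYKVGSC	1.48	3.07	FALSE	FALSE	FALSE
SYQRENESDEEEKNNEDGSC	1.64	2.38	FALSE	FALSE	FALSE
VEDNYGVTLRQPKYMGWGSC	1.41	2.36	FALSE	FALSE	FALSE
WNAMGKWKAMVDKTGDFGSC	2.1	2.4	FALSE	FALSE	FALSE
WNIHERHRFDQPYDYGHGSC	1.49	2.85	FALSE	FALSE	FALSE
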