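# Ir-192 bare point source emission line spectrum.
# energy in MeV; weight = photons per decay (unnormalized).
# Principal gamma lines and daughter K X-ray groups.
energy	weight
0.06512	0.0263
0.06683	0.0446
0.07582	0.0153
0.11043	0.00012
0.13634	0.00199
0.17698	0.000043
0.20131	0.00473
0.20580	0.0334
0.28327	0.00266
0.29596	0.2871
0.30846	0.2970
0.31651	0.8286
0.32917	0.000174
0.37449	0.00726
0.41647	0.00669
0.42052	0.00069
0.46807	0.4784
0.48458	0.03189
0.48906	0.00438
0.58858	0.04522
0.59349	0.00042
0.60441	0.08216
0.61246	0.0534
0.76580	0.00013
0.88454	0.00291
1.06148	0.00053
1.37820	0.000012
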