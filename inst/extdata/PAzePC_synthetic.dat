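# lipidxr reflectivity curve
# wavelength: 1.24
# normalized: false
# sample: PAzePC
# seed: 74233716
# columns: qz reflectivity sigma
0.016 1.00619231287 0.0201238462574
0.0165161840648 1.02188511133 0.0204377022266
0.017049021004 0.975196098255 0.0195039219651
0.0175990480642 1.01306613169 0.0202613226339
0.0181668198246 1.00927986731 0.0201855973461
0.018752908756 1.01376829777 0.0202753659553
0.0193579057978 1.01057664114 0.0202115328227
0.0199824209542 1.01211538855 0.020242307771
0.0206270839088 1.00562695634 0.0201125391268
0.0212925446599 1.01449172549 0.0202898345098
0.0219794741757 0.568145573194 0.0113629114639
0.0226885650709 0.313587436717 0.00627174873434
0.0234205323049 0.21167881459 0.00423357629179
0.0241761139027 0.15644343242 0.00312886864839
0.0249560716994 0.120786242899 0.00241572485798
0.0257611921076 0.0894342983127 0.00178868596625
0.0265922869112 0.0741586445724 0.00148317289145
0.0274501940831 0.0615398661891 0.00123079732378
0.0283357786308 0.0470465438369 0.000940930876737
0.0292499334679 0.0396435929799 0.000792871859598
0.030193580315 0.0332259551065 0.000664519102131
0.0311676706287 0.0286452684511 0.000572905369022
0.032173186561 0.0238387155265 0.00047677431053
0.0332111419496 0.0204305131314 0.000408610262629
0.0342825833402 0.0169296966589 0.000338593933178
0.0353885910415 0.0144800189489 0.000289600378977
0.0365302802148 0.0128329314261 0.000256658628521
0.037708801998 0.0108325722807 0.000216651445615
0.0389253446665 0.00879266931982 0.000175853386396
0.0401811348312 0.00811999381451 0.00016239987629
0.0414774386754 0.00682774690781 0.000136554938156
0.0428155632313 0.00576824055695 0.000115364811139
0.044196857698 0.00503646322157 0.000100729264431
0.0456227148017 0.00433022807772 8.66045615545e-05
0.0470945722001 0.00376930315446 7.53860630891e-05
0.048613913932 0.00331811779298 6.63623558595e-05
0.0501822719133 0.00289505549335 5.7901109867e-05
0.051801227482 0.00258986643527 5.17973287054e-05
0.0534724129923 0.00223614639198 4.47229278396e-05
0.0551975134608 0.00192072610176 3.84145220351e-05
0.056978268265 0.00169316588312 3.38633176625e-05
0.0588164728975 0.00150930178348 3.01860356695e-05
0.0607139807762 0.00131494610759 2.62989221518e-05
0.062672705113 0.00112730451631 2.25460903262e-05
0.064694620843 0.00102678162972 2.05356325944e-05
0.0667817666155 0.00089526358074 1.79052716148e-05
0.0689362468498 0.000805800041995 1.61160008399e-05
0.0711602338569 0.000689281278983 1.37856255797e-05
0.0734559700298 0.000605241891102 1.2104837822e-05
0.0758257701046 0.000525628208312 1.05125641662e-05
0.0782720234941 0.000468880262058 9.37760524117e-06
0.0807971966972 0.000408949367589 8.17898735178e-06
0.0834038357859 0.000371613954172 7.43227908343e-06
0.0860945689721 0.000318953418787 6.37906837574e-06
0.0888721092579 0.000296180425198 5.92360850397e-06
0.0917392571708 0.000256398996672 5.12797993343e-06
0.0946989035878 0.000230451530952 4.60903061904e-06
0.0977540326496 0.000199559084481 3.99118168961e-06
0.10090772477 0.000173690110026 3.47380220053e-06
0.104163159742 0.000155376860796 3.10753721592e-06
0.107523619942 0.000142659391207 2.85318782414e-06
0.110992493642 0.000123555599793 2.47111199586e-06
0.114573278426 0.00011070975275 2.214195055e-06
0.118269584712 9.44866216635e-05 1.88973243327e-06
0.122085139398 8.20668737902e-05 1.6413374758e-06
0.126023789618 7.47407888423e-05 1.49481577685e-06
0.130089506617 6.4849409314e-05 1.29698818628e-06
0.134286389762 5.55174219389e-05 1.11034843878e-06
0.13861867067 5.02402636651e-05 1.0048052733e-06
0.143090717475 4.41195955832e-05 8.82391911665e-07
0.147707039237 3.81436836395e-05 7.6287367279e-07
0.152472290482 3.35152088989e-05 6.70304177979e-07
0.157391275899 2.74010686992e-05 5.48021373984e-07
0.162468955184 2.50757596206e-05 5.01515192411e-07
0.16771044804 2.13779769956e-05 4.27559539912e-07
0.173121039339 1.85469718144e-05 3.70939436287e-07
0.178706184451 1.49882093061e-05 2.99764186123e-07
0.184471514745 1.30527068125e-05 2.6105413625e-07
0.190422843266 1.14801948182e-05 2.29603896364e-07
0.196566170595 9.74416379707e-06 1.94883275941e-07
0.202907690905 8.3081070417e-06 1.66162140834e-07
0.209453798197 6.77262394499e-06 1.354524789e-07
0.216211092756 5.90255960455e-06 1.18051192091e-07
0.223186387801 4.88625181364e-06 9.77250362729e-08
0.230386716356 3.8372140921e-06 7.67442818419e-08
0.237819338339 3.25313844242e-06 6.50627688483e-08
0.245491747887 2.47126423061e-06 4.94252846123e-08
0.253411680906 1.989773763e-06 3.97954752601e-08
0.261587122876 1.62146919521e-06 3.24293839042e-08
0.270026316901 1.22680878018e-06 2.45361756036e-08
0.278737772018 9.55615439293e-07 1.91123087859e-08
0.28773027178 7.36361581089e-07 1.47272316218e-08
0.297012883109 5.44328003894e-07 1.08865600779e-08
0.306594965441 4.0053721535e-07 8.01074430699e-09
0.31648618016 2.87993986597e-07 5.75987973195e-09
0.326696500344 1.93691343246e-07 3.87382686493e-09
0.337236220814 1.36853683148e-07 2.73707366297e-09
0.348115968518 9.12759652308e-08 1.82551930462e-09
0.359346713247 6.12448289576e-08 1.22489657915e-09
0.370939778693 3.73099217739e-08 7.46198435478e-10
0.382906853866 2.4663928187e-08 4.93278563739e-10
0.395260004884 1.6164577374e-08 3.23291547479e-10
0.408011687133 1.19011211082e-08 2.38022422165e-10
0.421174757831 9.70973089647e-09 1.94194617929e-10
0.434762488988 9.24774139981e-09 1.84954827996e-10
0.448788580788 8.83238302914e-09 1.76647660583e-10
0.463267175406 8.59026890777e-09 1.71805378155e-10
0.478212871262 8.46150678777e-09 1.69230135755e-10
0.493640737746 8.28330780504e-09 1.65666156101e-10
0.509566330408 7.7348593944e-09 1.54697187888e-10
0.526005706641 7.0021786664e-09 1.40043573328e-10
0.542975441877 6.12877831065e-09 1.22575566213e-10
0.560492646296 5.07535176377e-09 1.01507035275e-10
0.578574982075 4.25095478525e-09 1e-10
0.597240681204 3.36897387028e-09 1e-10
0.616508563861 2.66306078678e-09 1e-10
0.636398057392 2.02445131984e-09 1e-10
0.6569292159 1.49186023156e-09 1e-10
0.678122740461 1.07933124444e-09 1e-10
0.7 7.31575232886e-10 1e-10
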