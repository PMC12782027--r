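# lipidxr reflectivity curve
# wavelength: 1.24
# normalized: false
# sample: SAPC+15-LOX-2
# seed: 123925441
# columns: qz reflectivity sigma
0.016 1.03173876998 0.0206347753996
0.0165161840648 1.0324736036 0.0206494720719
0.017049021004 1.00145914765 0.020029182953
0.0175990480642 0.987045642584 0.0197409128517
0.0181668198246 0.973851111537 0.0194770222307
0.018752908756 0.957119770414 0.0191423954083
0.0193579057978 0.976523313765 0.0195304662753
0.0199824209542 1.03182642218 0.0206365284437
0.0206270839088 0.993902009569 0.0198780401914
0.0212925446599 0.983354170356 0.0196670834071
0.0219794741757 0.556498350785 0.0111299670157
0.0226885650709 0.316918835739 0.00633837671478
0.0234205323049 0.210088623172 0.00420177246345
0.0241761139027 0.156023523179 0.00312047046359
0.0249560716994 0.121206048969 0.00242412097939
0.0257611921076 0.0981783703784 0.00196356740757
0.0265922869112 0.0757544522416 0.00151508904483
0.0274501940831 0.0592083675077 0.00118416735015
0.0283357786308 0.0484794075535 0.00096958815107
0.0292499334679 0.0411276457603 0.000822552915207
0.030193580315 0.0354478681842 0.000708957363684
0.0311676706287 0.0293958284791 0.000587916569582
0.032173186561 0.0243741949013 0.000487483898027
0.0332111419496 0.0205142925262 0.000410285850524
0.0342825833402 0.0175539221456 0.000351078442912
0.0353885910415 0.0151175964496 0.000302351928992
0.0365302802148 0.0128568668783 0.000257137337567
0.037708801998 0.0113062005989 0.000226124011978
0.0389253446665 0.00938173607731 0.000187634721546
0.0401811348312 0.00829236155681 0.000165847231136
0.0414774386754 0.00699553560551 0.00013991071211
0.0428155632313 0.00620100281842 0.000124020056368
0.044196857698 0.00528371269421 0.000105674253884
0.0456227148017 0.00481574595163 9.63149190326e-05
0.0470945722001 0.00410718823126 8.21437646252e-05
0.048613913932 0.00350265411461 7.00530822923e-05
0.0501822719133 0.0031129051928 6.22581038561e-05
0.051801227482 0.00268829190633 5.37658381266e-05
0.0534724129923 0.00236616756724 4.73233513447e-05
0.0551975134608 0.00207063416159 4.14126832318e-05
0.056978268265 0.00189759523645 3.7951904729e-05
0.0588164728975 0.00164637696104 3.29275392208e-05
0.0607139807762 0.00145421895188 2.90843790377e-05
0.062672705113 0.00126395533723 2.52791067447e-05
0.064694620843 0.00110248275696 2.20496551392e-05
0.0667817666155 0.000974888782656 1.94977756531e-05
0.0689362468498 0.000861400203435 1.72280040687e-05
0.0711602338569 0.000742379974144 1.48475994829e-05
0.0734559700298 0.000684098048243 1.36819609649e-05
0.0758257701046 0.000601952893013 1.20390578603e-05
0.0782720234941 0.000531391145309 1.06278229062e-05
0.0807971966972 0.00046461302468 9.29226049361e-06
0.0834038357859 0.000416476022425 8.32952044849e-06
0.0860945689721 0.000375282975404 7.50565950809e-06
0.0888721092579 0.000310385862767 6.20771725534e-06
0.0917392571708 0.000295841683564 5.91683367129e-06
0.0946989035878 0.000252044686793 5.04089373585e-06
0.0977540326496 0.00022285801154 4.4571602308e-06
0.10090772477 0.000196816123272 3.93632246544e-06
0.104163159742 0.00017975644039 3.5951288078e-06
0.107523619942 0.000154203086262 3.08406172525e-06
0.110992493642 0.000131255934424 2.62511868848e-06
0.114573278426 0.000115861355537 2.31722711073e-06
0.118269584712 0.000103835150646 2.07670301293e-06
0.122085139398 9.25578709102e-05 1.8511574182e-06
0.126023789618 8.22803473593e-05 1.64560694719e-06
0.130089506617 7.04393283889e-05 1.40878656778e-06
0.134286389762 5.78727794284e-05 1.15745558857e-06
0.13861867067 5.28418130711e-05 1.05683626142e-06
0.143090717475 4.58011000663e-05 9.16022001326e-07
0.147707039237 3.83957446576e-05 7.67914893152e-07
0.152472290482 3.54764145033e-05 7.09528290066e-07
0.157391275899 2.88079914786e-05 5.76159829573e-07
0.162468955184 2.48064859889e-05 4.96129719778e-07
0.16771044804 2.11362303339e-05 4.22724606677e-07
0.173121039339 1.79706836492e-05 3.59413672983e-07
0.178706184451 1.52826580493e-05 3.05653160985e-07
0.184471514745 1.22069699841e-05 2.44139399683e-07
0.190422843266 1.03504077553e-05 2.07008155107e-07
0.196566170595 8.51341606661e-06 1.70268321332e-07
0.202907690905 7.23676221619e-06 1.44735244324e-07
0.209453798197 5.64520114072e-06 1.12904022814e-07
0.216211092756 4.64786321231e-06 9.29572642462e-08
0.223186387801 3.686754312e-06 7.37350862401e-08
0.230386716356 2.93357850783e-06 5.86715701566e-08
0.237819338339 2.1710802895e-06 4.34216057901e-08
0.245491747887 1.74694403568e-06 3.49388807136e-08
0.253411680906 1.28724370582e-06 2.57448741163e-08
0.261587122876 9.77227715791e-07 1.95445543158e-08
0.270026316901 6.77221029757e-07 1.35444205951e-08
0.278737772018 4.94753121947e-07 9.89506243894e-09
0.28773027178 3.68859166944e-07 7.37718333887e-09
0.297012883109 2.67810116042e-07 5.35620232084e-09
0.306594965441 1.72558267908e-07 3.45116535815e-09
0.31648618016 1.11255622157e-07 2.22511244314e-09
0.326696500344 7.53891043608e-08 1.50778208722e-09
0.337236220814 5.19943888807e-08 1.03988777761e-09
0.348115968518 3.71088138648e-08 7.42176277296e-10
0.359346713247 2.7971858271e-08 5.5943716542e-10
0.370939778693 2.24459421522e-08 4.48918843045e-10
0.382906853866 2.1033669323e-08 4.2067338646e-10
0.395260004884 1.89746379702e-08 3.79492759403e-10
0.408011687133 1.97309207154e-08 3.94618414309e-10
0.421174757831 1.9701348531e-08 3.9402697062e-10
0.434762488988 1.83548033944e-08 3.67096067888e-10
0.448788580788 1.74804845128e-08 3.49609690256e-10
0.463267175406 1.64557165572e-08 3.29114331144e-10
0.478212871262 1.46260271099e-08 2.92520542198e-10
0.493640737746 1.37859346715e-08 2.7571869343e-10
0.509566330408 1.18523610283e-08 2.37047220567e-10
0.526005706641 1.00665857832e-08 2.01331715664e-10
0.542975441877 8.19379242587e-09 1.63875848517e-10
0.560492646296 6.44460431364e-09 1.28892086273e-10
0.578574982075 5.13633783473e-09 1.02726756695e-10
0.597240681204 3.88633646793e-09 1e-10
0.616508563861 2.86161250986e-09 1e-10
0.636398057392 2.09536000753e-09 1e-10
0.6569292159 1.47568390598e-09 1e-10
0.678122740461 9.99836174123e-10 1e-10
0.7 6.56521526268e-10 1e-10
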