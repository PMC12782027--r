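# lipidxr reflectivity curve
# wavelength: 1.24
# normalized: false
# sample: DSPC
# seed: 52250572
# columns: qz reflectivity sigma
0.016 1.00964656856 0.0201929313712
0.0165161840648 1.01731656408 0.0203463312816
0.017049021004 0.983139179635 0.0196627835927
0.0175990480642 1.00128049056 0.0200256098111
0.0181668198246 1.00295278601 0.0200590557201
0.018752908756 1.00574150024 0.0201148300048
0.0193579057978 0.979616873493 0.0195923374699
0.0199824209542 1.00568134116 0.0201136268232
0.0206270839088 0.996458450095 0.0199291690019
0.0212925446599 0.995011560729 0.0199002312146
0.0219794741757 0.560432865254 0.0112086573051
0.0226885650709 0.322687359263 0.00645374718527
0.0234205323049 0.213409999566 0.00426819999132
0.0241761139027 0.157710667591 0.00315421335181
0.0249560716994 0.116508477083 0.00233016954166
0.0257611921076 0.0970040396941 0.00194008079388
0.0265922869112 0.077138165323 0.00154276330646
0.0274501940831 0.0628668593861 0.00125733718772
0.0283357786308 0.0503596674236 0.00100719334847
0.0292499334679 0.0414788724167 0.000829577448335
0.030193580315 0.0358126942314 0.000716253884628
0.0311676706287 0.0304136509668 0.000608273019336
0.032173186561 0.0249342693709 0.000498685387418
0.0332111419496 0.0215091081839 0.000430182163679
0.0342825833402 0.0182764969511 0.000365529939023
0.0353885910415 0.01611752917 0.0003223505834
0.0365302802148 0.0136602182158 0.000273204364316
0.037708801998 0.0118028958895 0.000236057917789
0.0389253446665 0.0102630475991 0.000205260951981
0.0401811348312 0.0085861880203 0.000171723760406
0.0414774386754 0.00773589476034 0.000154717895207
0.0428155632313 0.00661869029349 0.00013237380587
0.044196857698 0.0058334176512 0.000116668353024
0.0456227148017 0.00514651101234 0.000102930220247
0.0470945722001 0.00429148885249 8.58297770497e-05
0.048613913932 0.00381360953797 7.62721907594e-05
0.0501822719133 0.00351346936874 7.02693873748e-05
0.051801227482 0.00297902720121 5.95805440242e-05
0.0534724129923 0.00260311370056 5.20622740111e-05
0.0551975134608 0.00234607653827 4.69215307654e-05
0.056978268265 0.00210994010129 4.21988020258e-05
0.0588164728975 0.00179902677492 3.59805354983e-05
0.0607139807762 0.00165641522212 3.31283044423e-05
0.062672705113 0.00141996531525 2.83993063051e-05
0.064694620843 0.00126343911994 2.52687823988e-05
0.0667817666155 0.00111603957562 2.23207915124e-05
0.0689362468498 0.000959180142576 1.91836028515e-05
0.0711602338569 0.000836090014673 1.67218002935e-05
0.0734559700298 0.000750251142606 1.50050228521e-05
0.0758257701046 0.000683795387308 1.36759077462e-05
0.0782720234941 0.000596776328517 1.19355265703e-05
0.0807971966972 0.000540060805833 1.08012161167e-05
0.0834038357859 0.000476102215364 9.52204430728e-06
0.0860945689721 0.00041821555388 8.3643110776e-06
0.0888721092579 0.000369786709127 7.39573418255e-06
0.0917392571708 0.000314431104779 6.28862209558e-06
0.0946989035878 0.000283052890446 5.66105780891e-06
0.0977540326496 0.000244891237155 4.8978247431e-06
0.10090772477 0.000211842303811 4.23684607623e-06
0.104163159742 0.000182039824229 3.64079648458e-06
0.107523619942 0.000169916237225 3.39832474451e-06
0.110992493642 0.00013922639161 2.78452783221e-06
0.114573278426 0.000120164619009 2.40329238017e-06
0.118269584712 0.000106616558531 2.13233117061e-06
0.122085139398 9.03458685484e-05 1.80691737097e-06
0.126023789618 7.48494588114e-05 1.49698917623e-06
0.130089506617 6.30017364563e-05 1.26003472913e-06
0.134286389762 5.41229360025e-05 1.08245872005e-06
0.13861867067 4.54699565822e-05 9.09399131643e-07
0.143090717475 3.65740357201e-05 7.31480714403e-07
0.147707039237 2.98166218797e-05 5.96332437593e-07
0.152472290482 2.46315245657e-05 4.92630491314e-07
0.157391275899 2.02227959251e-05 4.04455918501e-07
0.162468955184 1.54245292765e-05 3.0849058553e-07
0.16771044804 1.21467221824e-05 2.42934443649e-07
0.173121039339 8.74473757152e-06 1.7489475143e-07
0.178706184451 6.39603284073e-06 1.27920656815e-07
0.184471514745 4.67284617516e-06 9.34569235031e-08
0.190422843266 3.18952462182e-06 6.37904924364e-08
0.196566170595 2.15049247267e-06 4.30098494534e-08
0.202907690905 1.37675198513e-06 2.75350397026e-08
0.209453798197 8.66294889568e-07 1.73258977914e-08
0.216211092756 5.73049326771e-07 1.14609865354e-08
0.223186387801 4.28694124386e-07 8.57388248772e-09
0.230386716356 4.39672641493e-07 8.79345282985e-09
0.237819338339 5.28691410593e-07 1.05738282119e-08
0.245491747887 6.5595951817e-07 1.31191903634e-08
0.253411680906 8.4662012948e-07 1.69324025896e-08
0.261587122876 1.02499766314e-06 2.04999532628e-08
0.270026316901 1.17395529886e-06 2.34791059773e-08
0.278737772018 1.350934611e-06 2.70186922201e-08
0.28773027178 1.37291701705e-06 2.7458340341e-08
0.297012883109 1.48060305139e-06 2.96120610278e-08
0.306594965441 1.43166116724e-06 2.86332233449e-08
0.31648618016 1.37950009655e-06 2.75900019311e-08
0.326696500344 1.32037321655e-06 2.64074643311e-08
0.337236220814 1.20105670846e-06 2.40211341692e-08
0.348115968518 1.02102389429e-06 2.04204778858e-08
0.359346713247 8.66010407106e-07 1.73202081421e-08
0.370939778693 6.67127615165e-07 1.33425523033e-08
0.382906853866 5.28868936119e-07 1.05773787224e-08
0.395260004884 4.00664823176e-07 8.01329646353e-09
0.408011687133 2.79772850766e-07 5.59545701532e-09
0.421174757831 1.78280080838e-07 3.56560161676e-09
0.434762488988 1.10513058008e-07 2.21026116015e-09
0.448788580788 5.55414772867e-08 1.11082954573e-09
0.463267175406 2.25673178325e-08 4.5134635665e-10
0.478212871262 6.31211150053e-09 1.26242230011e-10
0.493640737746 6.26241191336e-10 1e-10
0.509566330408 1.69917811429e-09 1e-10
0.526005706641 5.62088426e-09 1.124176852e-10
0.542975441877 9.92986309814e-09 1.98597261963e-10
0.560492646296 1.22305758662e-08 2.44611517324e-10
0.578574982075 1.28226489464e-08 2.56452978928e-10
0.597240681204 1.15286027686e-08 2.30572055372e-10
0.616508563861 8.9166088348e-09 1.78332176696e-10
0.636398057392 6.05845613376e-09 1.21169122675e-10
0.6569292159 3.37990995692e-09 1e-10
0.678122740461 1.51689476025e-09 1e-10
0.7 5.03843633975e-10 1e-10
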