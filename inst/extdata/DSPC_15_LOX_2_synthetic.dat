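# lipidxr reflectivity curve
# wavelength: 1.24
# normalized: false
# sample: DSPC+15-LOX-2
# seed: 124281796
# columns: qz reflectivity sigma
0.016 0.995871786073 0.0199174357215
0.0165161840648 1.0034748434 0.0200694968681
0.017049021004 0.99789245004 0.0199578490008
0.0175990480642 1.01938381513 0.0203876763025
0.0181668198246 0.994567553896 0.0198913510779
0.018752908756 1.00497570927 0.0200995141854
0.0193579057978 1.01896374699 0.0203792749398
0.0199824209542 0.990225524727 0.0198045104945
0.0206270839088 0.986529039438 0.0197305807888
0.0212925446599 0.988125031115 0.0197625006223
0.0219794741757 0.571269133994 0.0114253826799
0.0226885650709 0.325239287309 0.00650478574618
0.0234205323049 0.219803883059 0.00439607766118
0.0241761139027 0.15876634259 0.00317532685181
0.0249560716994 0.122160735101 0.00244321470202
0.0257611921076 0.0949861145991 0.00189972229198
0.0265922869112 0.0787047082875 0.00157409416575
0.0274501940831 0.0604099365435 0.00120819873087
0.0283357786308 0.0500602739201 0.0010012054784
0.0292499334679 0.0430678549281 0.000861357098563
0.030193580315 0.0351205686733 0.000702411373465
0.0311676706287 0.0306701933652 0.000613403867305
0.032173186561 0.0242549383343 0.000485098766687
0.0332111419496 0.0214587061408 0.000429174122817
0.0342825833402 0.018831505209 0.00037663010418
0.0353885910415 0.0158929307767 0.000317858615533
0.0365302802148 0.0135415593005 0.000270831186009
0.037708801998 0.011829342029 0.000236586840581
0.0389253446665 0.0101480599217 0.000202961198433
0.0401811348312 0.00886846444874 0.000177369288975
0.0414774386754 0.0074678545088 0.000149357090176
0.0428155632313 0.00679722161604 0.000135944432321
0.044196857698 0.00585810112891 0.000117162022578
0.0456227148017 0.00529680941388 0.000105936188278
0.0470945722001 0.00442034035797 8.84068071594e-05
0.048613913932 0.00393600315462 7.87200630924e-05
0.0501822719133 0.00343106385333 6.86212770665e-05
0.051801227482 0.00302056126317 6.04112252635e-05
0.0534724129923 0.00267423367648 5.34846735295e-05
0.0551975134608 0.00239530426603 4.79060853207e-05
0.056978268265 0.0021786543582 4.35730871641e-05
0.0588164728975 0.00180949766825 3.61899533649e-05
0.0607139807762 0.00163736044346 3.27472088691e-05
0.062672705113 0.00148050400841 2.96100801682e-05
0.064694620843 0.00124907108777 2.49814217553e-05
0.0667817666155 0.00112061814014 2.24123628029e-05
0.0689362468498 0.000950466087654 1.90093217531e-05
0.0711602338569 0.000889189705376 1.77837941075e-05
0.0734559700298 0.000796034664029 1.59206932806e-05
0.0758257701046 0.000706632109276 1.41326421855e-05
0.0782720234941 0.000600587017722 1.20117403544e-05
0.0807971966972 0.000541640249715 1.08328049943e-05
0.0834038357859 0.000473589132806 9.47178265611e-06
0.0860945689721 0.00041275147638 8.25502952759e-06
0.0888721092579 0.000351215407624 7.02430815247e-06
0.0917392571708 0.000312703730261 6.25407460522e-06
0.0946989035878 0.000286059082192 5.72118164385e-06
0.0977540326496 0.000245052036187 4.90104072374e-06
0.10090772477 0.000213723941964 4.27447883928e-06
0.104163159742 0.000193666362775 3.87332725549e-06
0.107523619942 0.000157185419469 3.14370838938e-06
0.110992493642 0.000139970837233 2.79941674467e-06
0.114573278426 0.000117970961001 2.35941922001e-06
0.118269584712 0.000100425994 2.00851988001e-06
0.122085139398 8.89376863573e-05 1.77875372715e-06
0.126023789618 7.15984320774e-05 1.43196864155e-06
0.130089506617 6.17975344584e-05 1.23595068917e-06
0.134286389762 5.02618928711e-05 1.00523785742e-06
0.13861867067 4.15756300823e-05 8.31512601646e-07
0.143090717475 3.51253196569e-05 7.02506393137e-07
0.147707039237 2.67502646354e-05 5.35005292707e-07
0.152472290482 2.2485998617e-05 4.4971997234e-07
0.157391275899 1.82661004465e-05 3.6532200893e-07
0.162468955184 1.34484469382e-05 2.68968938764e-07
0.16771044804 1.01249765035e-05 2.02499530069e-07
0.173121039339 7.76422963594e-06 1.55284592719e-07
0.178706184451 5.54353351801e-06 1.1087067036e-07
0.184471514745 3.93673607743e-06 7.87347215486e-08
0.190422843266 2.68144623908e-06 5.36289247815e-08
0.196566170595 1.78245754825e-06 3.56491509651e-08
0.202907690905 1.16338298224e-06 2.32676596449e-08
0.209453798197 7.73169643178e-07 1.54633928636e-08
0.216211092756 6.19886070133e-07 1.23977214027e-08
0.223186387801 5.85214934136e-07 1.17042986827e-08
0.230386716356 6.54884566961e-07 1.30976913392e-08
0.237819338339 8.01847927057e-07 1.60369585411e-08
0.245491747887 9.51221446336e-07 1.90244289267e-08
0.253411680906 1.16694983086e-06 2.33389966172e-08
0.261587122876 1.32861060111e-06 2.65722120222e-08
0.270026316901 1.50683412794e-06 3.01366825587e-08
0.278737772018 1.65560481853e-06 3.31120963705e-08
0.28773027178 1.57199341832e-06 3.14398683663e-08
0.297012883109 1.68357902997e-06 3.36715805994e-08
0.306594965441 1.59473651194e-06 3.18947302387e-08
0.31648618016 1.49047239209e-06 2.98094478418e-08
0.326696500344 1.36138088247e-06 2.72276176493e-08
0.337236220814 1.2194088206e-06 2.4388176412e-08
0.348115968518 1.01154169878e-06 2.02308339755e-08
0.359346713247 8.72656430919e-07 1.74531286184e-08
0.370939778693 6.92870054637e-07 1.38574010927e-08
0.382906853866 5.07108760087e-07 1.01421752017e-08
0.395260004884 3.73398815685e-07 7.46797631371e-09
0.408011687133 2.52636377089e-07 5.05272754177e-09
0.421174757831 1.55495477492e-07 3.10990954983e-09
0.434762488988 8.38482240416e-08 1.67696448083e-09
0.448788580788 4.01587752225e-08 8.03175504451e-10
0.463267175406 1.49956517889e-08 2.99913035778e-10
0.478212871262 3.55840713169e-09 1e-10
0.493640737746 1.57015981993e-09 1e-10
0.509566330408 4.23290106917e-09 1e-10
0.526005706641 8.23964363123e-09 1.64792872625e-10
0.542975441877 1.10725028526e-08 2.21450057051e-10
0.560492646296 1.33496785728e-08 2.66993571456e-10
0.578574982075 1.31109886538e-08 2.62219773077e-10
0.597240681204 1.06545051489e-08 2.13090102978e-10
0.616508563861 8.31766448646e-09 1.66353289729e-10
0.636398057392 5.57952837544e-09 1.11590567509e-10
0.6569292159 3.35036607078e-09 1e-10
0.678122740461 1.65784599294e-09 1e-10
0.7 6.66977613531e-10 1e-10
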