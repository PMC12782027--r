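# lipidxr reflectivity curve
# wavelength: 1.24
# normalized: false
# sample: SAPC
# seed: 51894217
# columns: qz reflectivity sigma
0.016 1.00714033231 0.0201428066463
0.0165161840648 0.985612022547 0.0197122404509
0.017049021004 0.991204791734 0.0198240958347
0.0175990480642 1.01197322916 0.0202394645833
0.0181668198246 1.0050798502 0.0201015970041
0.018752908756 0.974170026803 0.0194834005361
0.0193579057978 1.03248846216 0.0206497692431
0.0199824209542 0.975193937017 0.0195038787403
0.0206270839088 1.01052593206 0.0202105186411
0.0212925446599 1.04017828595 0.0208035657191
0.0219794741757 0.56865541855 0.011373108371
0.0226885650709 0.310308160551 0.00620616321101
0.0234205323049 0.207723400965 0.0041544680193
0.0241761139027 0.14923486327 0.00298469726541
0.0249560716994 0.119398060981 0.00238796121961
0.0257611921076 0.0916336624728 0.00183267324946
0.0265922869112 0.0710377472148 0.0014207549443
0.0274501940831 0.0605447977004 0.00121089595401
0.0283357786308 0.0490782049221 0.000981564098442
0.0292499334679 0.041433012291 0.000828660245819
0.030193580315 0.0333326072467 0.000666652144934
0.0311676706287 0.0279136634747 0.000558273269493
0.032173186561 0.0242897082304 0.000485794164609
0.0332111419496 0.0210884598997 0.000421769197995
0.0342825833402 0.0177477384961 0.000354954769922
0.0353885910415 0.0145583661116 0.000291167322231
0.0365302802148 0.0125500711389 0.000251001422778
0.037708801998 0.0106603735738 0.000213207471475
0.0389253446665 0.00908086483299 0.00018161729666
0.0401811348312 0.00789036392259 0.000157807278452
0.0414774386754 0.0068987135276 0.000137974270552
0.0428155632313 0.00608489386383 0.000121697877277
0.044196857698 0.00515593744443 0.000103118748889
0.0456227148017 0.00451866692472 9.03733384943e-05
0.0470945722001 0.00392693490727 7.85386981454e-05
0.048613913932 0.00345848970624 6.91697941249e-05
0.0501822719133 0.00302264122848 6.04528245697e-05
0.051801227482 0.00262836326932 5.25672653865e-05
0.0534724129923 0.00228075900643 4.56151801285e-05
0.0551975134608 0.00197007419155 3.94014838311e-05
0.056978268265 0.00172786234608 3.45572469216e-05
0.0588164728975 0.00155859755353 3.11719510706e-05
0.0607139807762 0.00138729796318 2.77459592636e-05
0.062672705113 0.00117446028315 2.34892056629e-05
0.064694620843 0.00105256183067 2.10512366134e-05
0.0667817666155 0.000937496959234 1.87499391847e-05
0.0689362468498 0.000821756479775 1.64351295955e-05
0.0711602338569 0.000713482624611 1.42696524922e-05
0.0734559700298 0.000639604328693 1.27920865739e-05
0.0758257701046 0.000578011508475 1.15602301695e-05
0.0782720234941 0.000502969334017 1.00593866803e-05
0.0807971966972 0.000432594657042 8.65189314084e-06
0.0834038357859 0.000376507737341 7.53015474682e-06
0.0860945689721 0.000323271076526 6.46542153052e-06
0.0888721092579 0.000296168902709 5.92337805418e-06
0.0917392571708 0.000260206291222 5.20412582443e-06
0.0946989035878 0.000233246474372 4.66492948743e-06
0.0977540326496 0.000202337278031 4.04674556063e-06
0.10090772477 0.000180704091063 3.61408182126e-06
0.104163159742 0.000154970896267 3.09941792534e-06
0.107523619942 0.00013367597429 2.67351948579e-06
0.110992493642 0.000120480931514 2.40961863028e-06
0.114573278426 0.000104849093768 2.09698187537e-06
0.118269584712 9.23684669944e-05 1.84736933989e-06
0.122085139398 8.16890224492e-05 1.63378044898e-06
0.126023789618 6.85202263076e-05 1.37040452615e-06
0.130089506617 5.91024754602e-05 1.1820495092e-06
0.134286389762 5.04702513416e-05 1.00940502683e-06
0.13861867067 4.53008954245e-05 9.06017908489e-07
0.143090717475 3.78139906668e-05 7.56279813336e-07
0.147707039237 3.22044245337e-05 6.44088490675e-07
0.152472290482 2.92193588557e-05 5.84387177115e-07
0.157391275899 2.38510936928e-05 4.77021873857e-07
0.162468955184 2.04180977082e-05 4.08361954165e-07
0.16771044804 1.69646545604e-05 3.39293091207e-07
0.173121039339 1.36539121089e-05 2.73078242178e-07
0.178706184451 1.14179470094e-05 2.28358940187e-07
0.184471514745 9.23787819992e-06 1.84757563998e-07
0.190422843266 7.46407187333e-06 1.49281437467e-07
0.196566170595 6.13885938168e-06 1.22777187634e-07
0.202907690905 4.72344301663e-06 9.44688603326e-08
0.209453798197 3.70375524706e-06 7.40751049412e-08
0.216211092756 2.8698680968e-06 5.7397361936e-08
0.223186387801 2.07961040349e-06 4.15922080697e-08
0.230386716356 1.58005547675e-06 3.16011095349e-08
0.237819338339 1.16254130713e-06 2.32508261427e-08
0.245491747887 7.72760778574e-07 1.54552155715e-08
0.253411680906 5.72642860272e-07 1.14528572054e-08
0.261587122876 3.68040719419e-07 7.36081438838e-09
0.270026316901 2.43873709282e-07 4.87747418565e-09
0.278737772018 1.50666701429e-07 3.01333402858e-09
0.28773027178 9.46208242347e-08 1.89241648469e-09
0.297012883109 6.73035853897e-08 1.34607170779e-09
0.306594965441 5.54307777886e-08 1.10861555577e-09
0.31648618016 5.49875521422e-08 1.09975104284e-09
0.326696500344 6.04943141084e-08 1.20988628217e-09
0.337236220814 7.12481806682e-08 1.42496361336e-09
0.348115968518 7.75016735702e-08 1.5500334714e-09
0.359346713247 8.83132916565e-08 1.76626583313e-09
0.370939778693 8.92038916255e-08 1.78407783251e-09
0.382906853866 8.77981964078e-08 1.75596392816e-09
0.395260004884 8.73697328446e-08 1.74739465689e-09
0.408011687133 8.2515767407e-08 1.65031534814e-09
0.421174757831 7.42561117328e-08 1.48512223466e-09
0.434762488988 6.69164326719e-08 1.33832865344e-09
0.448788580788 5.49274781011e-08 1.09854956202e-09
0.463267175406 4.79120467516e-08 9.58240935032e-10
0.478212871262 3.88392551389e-08 7.76785102778e-10
0.493640737746 3.1419243613e-08 6.28384872259e-10
0.509566330408 2.36727034533e-08 4.73454069066e-10
0.526005706641 1.75376812725e-08 3.5075362545e-10
0.542975441877 1.22757585067e-08 2.45515170134e-10
0.560492646296 8.80941417498e-09 1.761882835e-10
0.578574982075 5.7705333931e-09 1.15410667862e-10
0.597240681204 3.78021444242e-09 1e-10
0.616508563861 2.28544358397e-09 1e-10
0.636398057392 1.39438422427e-09 1e-10
0.6569292159 7.77151401853e-10 1e-10
0.678122740461 4.22028874243e-10 1e-10
0.7 2.11451797025e-10 1e-10
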