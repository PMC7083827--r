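LM=11
0.15251019676049687 3.0004490640502732
-5.4923928802228472 1.5627434317983089
3.4558794193231903 2.5598233662341028
5.7087844329789172 0.73347325520038842
6.1796292122146577 -0.76523846501370307
-5.7109619338708031 -0.73836775537517885
4.4285442314924808 -2.3239703309978377
0.51206866472904811 -2.8811209777455415
-4.002097966752781 -2.4434018002297337
-5.9496813362162007 0.35561617490591757
-5.061896992274054 -1.8081115739112688
ID=o1
SCALE=1.0
LM=11
0.016523707415811124 3.1806124750270128
-5.2014616783048373 1.75320727928279
3.4578002048154466 2.647302897271524
5.7131769227965972 0.88122116986636845
5.9462781917096876 -0.54624342065718812
-5.8267608263563977 -0.98697166130714598
4.3150460712669831 -2.322023463037056
0.63189539101206504 -2.6912700566571219
-3.8910395857256113 -2.5021261143997897
-6.08041779681135 0.36417209989183824
-5.1699387926855724 -1.8654456380362476
ID=o2
SCALE=1.0
LM=11
0.12449089244922557 3.1575725186785877
-5.1699464480463195 1.6578080041754841
3.579147334394241 2.5336576809090556
5.6059036047454267 0.76899640749527132
6.210145577123134 -0.89407271751096618
-5.9502229046925166 -1.0012601505884522
4.5326142592559515 -2.3384648083737414
0.82600821276598047 -2.8064234885371566
-4.0164221811001743 -2.4344565646670979
-5.714506040317886 0.4629689249855134
-5.2476214528123126 -1.8781240363520912
ID=o3
SCALE=1.0
LM=11
0.0071271932415211126 3.0202901316497055
-5.5342213561643767 1.6303671105762749
3.3432530141972814 2.2973891920449576
5.7938113148465655 0.75421741758168592
6.0956569035706867 -0.67571039425174617
-5.8353871489682341 -0.83330233060019498
4.0854739449160027 -2.0167804543008381
0.59500577532092291 -2.793208007165553
-3.7236175419432942 -2.8175155031187629
-5.9377617739401787 0.38592100543229152
-5.2348882345357728 -1.869871867737501
ID=p1
SCALE=1.0
LM=11
-0.17359470892652629 2.8213717619442096
-5.5861468948702191 1.6806577605976418
3.4066807815679283 2.5082947694018771
5.5709194197806458 0.86104485308271039
6.0007120313404929 -0.46043254112833365
-5.8420170378659693 -0.58970135986610728
4.3452623845863414 -1.9592000814957431
0.30230560288689085 -2.8952763512152973
-4.090530387571393 -2.5298614465370495
-6.1806015466000899 0.34389315684820349
-5.2136170290855759 -2.0285134640877218
ID=f1
SCALE=1.0
LM=11
-0.17893323759192303 3.0192543272248638
-5.3501795749513441 1.749454897750472
3.5487636419839386 2.3552008918004073
5.3268751124896916 1.0868155223859499
6.1662327279596223 -0.78139619704285646
-5.7004906011581005 -0.66991891498992673
4.093959080526667 -2.0538948518178102
0.48810428178858217 -2.8671201921057046
-3.8244972623301909 -2.561890359757101
-6.2126245536380011 0.17212383149470448
-5.0567606630216178 -1.9624658968746065
ID=f2
SCALE=1.0
LM=11
-0.0028244875536771012 2.9460446699938365
-5.7910871983875136 1.8013157337054584
3.6435280737362974 2.3639756883426091
5.2703750770481248 0.94030264657945739
6.3366559953125403 -0.85463165529997165
-5.9997412834023116 -0.68056545925558354
4.3209461065419834 -1.8988709202635812
0.7016649497518922 -2.7261872183941858
-3.8205361322239613 -2.9030929498269895
-6.3313325831692326 0.22850650823323021
-5.0100420893881976 -2.0128878933902592
ID=f3
SCALE=1.0
LM=11
-0.10353719279977305 2.8640867415756803
-5.4251381521327469 1.8227328630865196
3.603599901717311 2.4993028070848631
5.2272430415039359 0.95220044919521052
6.1424433281382003 -0.7050020326865799
-5.9965371246951431 -0.73252019410276747
4.3277067873894426 -2.1963837648040312
0.56928354657166147 -2.7306165890358796
-3.6925721293968081 -2.7505449775477242
-6.4546098120225981 0.16406082615100526
-5.0453228305888063 -1.9089248978515376
ID=f4
SCALE=1.0
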