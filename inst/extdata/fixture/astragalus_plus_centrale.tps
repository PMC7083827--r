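LM=11
0.19219432604568651 3.0735067723742113
-5.3623067388701129 1.3886151691690856
3.4859704515461178 2.5753609115948368
5.8390825505792447 0.86938135683971418
5.9742155633594711 -0.54671561907486366
-5.8284137049205764 -0.72458946636758115
4.0085318356926072 -2.0250852791589611
0.45339231407347153 -2.9900372085616311
-3.8864727492380826 -2.6072555747247295
-6.1447423758741104 0.37277759566031798
-4.8410733327185245 -1.9147996901869826
ID=o1
SCALE=1.0
LM=11
0.30248633442656497 2.8185568059925217
-5.5578370715561913 1.5550246414467366
3.7358300165968616 2.5884637950907878
5.7028213380288406 1.0303418843771777
5.950753877709916 -0.68746118107721832
-5.899045109114347 -0.74170280845141678
4.0031916268755978 -2.0148568425268398
0.50378019334829638 -2.8831805254052378
-3.6158517147352924 -2.0901942767572339
-6.1682779630535336 0.49481506616585857
-4.9007683135032858 -2.2669854129298064
ID=o2
SCALE=1.0
LM=11
0.10709814106096578 2.9561400265679874
-5.4006665850871398 1.8117099818059763
3.6095556443463792 2.6602347378625537
5.7510413034325243 0.77545268253127775
5.9421567274832094 -0.595993686160042
-6.0097336543637683 -0.83339051464092817
4.1022972585396573 -2.1300010746702651
0.49451854318333227 -2.7726253166742652
-3.5338055545809803 -2.4093658170655354
-6.2360958884145763 0.35660371917761802
-5.014998417109811 -2.2438689581623059
ID=o3
SCALE=1.0
LM=11
0.20688723217187244 3.1888664690736892
-5.57610465177655 1.5249044474973885
3.3935555743233703 2.3289414006251405
5.5845238272540829 0.86574956899559663
6.1251304251892718 -0.71613733002971802
-6.0652603205431017 -0.99590065149909068
4.1543053105028678 -1.9962207039054236
0.71208650271984142 -3.1042079267963794
-3.6031256694070284 -2.6065430062235713
-5.9520376340055403 0.31381678995759155
-4.8884955372158263 -1.823679401238065
ID=p1
SCALE=1.0
LM=11
-0.30487822948609872 2.894104848816915
-6.0341816020366723 1.6075100188583757
3.4884223051160821 2.6065768789123656
5.5530774281850555 0.67128075760925621
5.9196204623652093 -0.87143310228129556
-6.1880124632931031 -0.95157917603527098
4.4982288700097719 -2.3894313438925576
0.40454021705512855 -3.0374752829348948
-4.4710962838984676 -2.845930600185735
-6.5765169695535288 0.48634102151134911
-5.5432368707773474 -2.0185828678220044
ID=f1
SCALE=1.0
LM=11
-0.080698958847474911 2.6128316012383737
-6.0242459876440924 1.5981913940162638
3.5484621758425545 2.5197528246384517
5.6606591035750959 0.93403122953438034
5.9192084725431062 -0.65886239577810501
-6.377562697322154 -1.0514705494310845
4.6247443153360477 -2.1294746603725763
0.27557903459948452 -3.1611335884366714
-4.2874178766875248 -2.5863739868745661
-6.1721917749654542 0.44130109184971567
-5.7260446972578469 -1.9204812671371423
ID=f2
SCALE=1.0
LM=11
-0.10032682420808012 2.830628908453984
-6.0060874680182152 1.6464675114193608
3.4868494381823725 2.6741829396317525
5.6752624685390876 0.94380225379479488
5.7815911549137695 -0.77461575622960399
-6.3421723534095422 -0.70626828434237998
4.5094309007671303 -2.2859574749628968
0.26512664502520095 -3.032963484612174
-4.536811696557927 -2.4530749640684415
-6.2697990333308375 0.24796704398514657
-5.642260555569516 -1.9308129361839352
ID=f3
SCALE=1.0
LM=11
-0.054034986771716122 2.7811364304208177
-5.9599821314767301 1.6357690627860377
3.5899386437846093 2.5945409208426811
5.5918029395595958 0.88224529576929445
6.0722963328874764 -0.77880897643940872
-6.411219539109184 -0.6436870852821891
4.2686576194464996 -2.4096670041613861
0.39091666003938225 -2.8838790756794155
-4.550312902653749 -2.6432523187260859
-6.3738659546447725 0.38452225984660704
-5.6352691504683632 -1.8678886843672948
ID=f4
SCALE=1.0
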