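time_h,rep1,rep2,rep3
0,0.0869665644486417,0.0851353896978695,0.0855872012125029
0.166666666666667,0.0846336613379653,0.0861195574997363,0.0855006309855984
0.333333333333333,0.0857926935929036,0.0870014552249744,0.0870226808733235
0.5,0.0868656388254166,0.0875031825312969,0.0885721950181653
0.666666666666667,0.0873158113867923,0.0891509315313977,0.0886152602069855
0.833333333333333,0.0883922395062813,0.0899225297237378,0.0892632843297513
1,0.0911178801410299,0.0914879617212639,0.0891211922250302
1.16666666666667,0.0916939331142531,0.0929658855867148,0.0927416199388464
1.33333333333333,0.093484178832313,0.0939978463117369,0.0927893844950925
1.5,0.0971882325273815,0.0954952139132822,0.0958585778027562
1.66666666666667,0.0973987320261652,0.0961603694550397,0.0978959332024777
1.83333333333333,0.10201138411855,0.0986680372063354,0.0996436160877988
2,0.104142500833113,0.100915047137149,0.102955188794739
2.16666666666667,0.104977595182147,0.102936425745762,0.103848774540582
2.33333333333333,0.109918328830476,0.106433306798654,0.10833509552046
2.5,0.112012057042509,0.110502632618595,0.11251528082675
2.66666666666667,0.11457090954965,0.11495674332621,0.115911796090371
2.83333333333333,0.119877132847073,0.120171102959969,0.121463768029351
3,0.125493133189249,0.128576774833863,0.123678435233507
3.16666666666667,0.132743164745753,0.131888963255153,0.130293118698503
3.33333333333333,0.139316780857628,0.138157635281273,0.138380221524941
3.5,0.146773558722829,0.145784537680459,0.146044246530554
3.66666666666667,0.156351442796585,0.153716874082939,0.155069016188995
3.83333333333333,0.161762792507683,0.162728624817808,0.16390621374186
4,0.177232512615579,0.174446187643497,0.1734421385223
4.16666666666667,0.187734806356817,0.186741955891368,0.188302153191272
4.33333333333333,0.202927027736646,0.200793611144063,0.20209312656351
4.5,0.218541943742405,0.213407092265046,0.214880329428835
4.66666666666667,0.232866761145156,0.236552393903535,0.234332261919531
4.83333333333333,0.254716095525505,0.25963275660535,0.258238407340528
5,0.275903532933583,0.276526197069862,0.275804664212205
5.16666666666667,0.306395960282018,0.306090579466586,0.303571322092534
5.33333333333333,0.333834575293354,0.334254605313092,0.335736851243254
5.5,0.366261098353045,0.369664611520736,0.36363595836619
5.66666666666667,0.402254964175563,0.401639360995565,0.39757183789531
5.83333333333333,0.443731741047461,0.451249943216279,0.451531407504021
6,0.498987897990568,0.486485305752403,0.500112164059968
6.16666666666667,0.542052931109503,0.545680542293572,0.548016756627255
6.33333333333333,0.608305434158406,0.608254429033838,0.611280060067616
6.5,0.680380786494016,0.681770612652115,0.678880124001268
6.66666666666667,0.765598171387384,0.760782374095284,0.756376962838854
6.83333333333333,0.838716210595049,0.843932269712548,0.850897607915932
7,0.941708904499897,0.933374884498032,0.954294573575879
7.16666666666667,1.04344987391184,1.06049433987295,1.05385467934025
7.33333333333333,1.18015283996282,1.16592561908328,1.18860519396562
7.5,1.27487076386773,1.29275160545153,1.2887987818773
7.66666666666667,1.29740388175387,1.29316445754518,1.28410567807147
7.83333333333333,1.28758964485329,1.29079916243202,1.25572198960723
8,1.28128737279232,1.28153792935912,1.25039618480086
8.16666666666667,1.29197337541833,1.27455554716153,1.28619560911194
8.33333333333333,1.27664131221811,1.28588775581148,1.29517442655963
8.5,1.27990185202277,1.28828330063945,1.26355895597004
8.66666666666667,1.28470819633706,1.28785157394883,1.28790621267391
8.83333333333333,1.30203926838683,1.26866855036783,1.28328153790157
9,1.28929747957846,1.29991516080471,1.2893503256112
9.16666666666667,1.28617209452164,1.26420370515644,1.2970613259218
9.33333333333333,1.26008779296105,1.29420233952022,1.28188501531415
9.5,1.28408009263804,1.29264150301677,1.27236157805871
9.66666666666667,1.28212645494712,1.28390132120691,1.30837430395307
9.83333333333333,1.26853285657727,1.26025350575443,1.31013633705735
10,1.28097792824699,1.30025316224368,1.29460907103499
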