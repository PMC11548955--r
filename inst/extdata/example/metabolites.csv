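metabolite,T01_r1,T01_r2,T02_r1,T02_r2,T03_r1,T03_r2,T04_r1,T04_r2,T05_r1,T05_r2,T06_r1,T06_r2,T07_r1,T07_r2,T08_r1,T08_r2,T09_r1,T09_r2
target_met,11.1513080242574,12.3358550255861,13.8765150663114,12.1087588999546,30.2989250965703,28.1298393055955,50.3820872130160,47.7660693746535,57.1481453581688,55.7832637293187,58.2986351332910,59.7970016193230,43.3609917215576,48.9817121048848,28.1393178889180,29.0234343741068,11.6176368257899,12.0339166906857
met01,33.4362238902470,30.2694945840742,32.0131769426796,28.7892079612941,48.8874561354423,48.8778507492285,67.4518170301496,64.6312460517915,71.7623397215506,75.8489292782095,73.5456769963211,73.2386305399885,53.7887691621312,56.5760210358416,40.5986787312571,36.3371062296870,30.6853033870320,29.4334984704077
met02,42.4133206678581,43.3493040217805,43.5685157267340,43.2226509259642,54.0023365319096,49.9972911771139,58.0969839723423,56.4478140935450,63.8328772173352,63.8120471585031,58.4621120789744,58.6096385062051,45.3216511595970,43.5935666692975,43.6967994509038,44.8431717480587,44.3473640505128,44.1744733711664
met03,37.6863325235938,33.4015555715365,28.7761807505125,30.7929016000260,35.0585943873902,34.7917894259129,45.4034380133066,48.0697817234725,62.6398899831327,63.0329321271005,64.1277361485633,68.3716172387147,67.1666425582801,67.1057193012738,61.0092869434327,65.2127135559370,46.4574676390033,46.8864323792027
met04,39.0471509110983,38.0325026736519,28.9095791874522,27.9799301812213,54.6508286182850,51.5923625409397,68.7463555492708,71.9758936764014,69.9140765460429,70.5463813900397,73.9510548633381,76.4882247261335,48.0505031166858,55.0544578544672,20.7368271604393,23.4958340602510,35.3055956765600,32.3096962539724
met05,31.3241130870926,32.6608637156083,32.5126276869525,33.1774280069119,58.6212318529575,59.5957937442761,58.4054798240466,56.0167088123252,53.5824101630385,59.3651391733256,80.3882697772065,81.6520155840918,63.7901073740333,61.4866175524635,23.7456422521226,26.9422638725026,33.6631042262697,33.4467377442284
met06,38.7223037063520,46.7128404030450,25.2875363750385,18.2041477775861,33.7132931059415,29.2748353679217,50.0440004919739,49.5582143215624,48.6989576756303,47.3563976336080,73.3525352207113,68.7832603510472,73.4988586040940,71.9029221980465,56.5368194023581,57.9289753002069,57.4191909888236,55.1053821878084
met07,63.5414349901522,59.9432463319031,30.2684524223437,33.3404574196253,48.7443886291674,48.0065685145768,59.4183395208165,57.0253279510346,30.2705579062093,31.8035918731587,56.1681367529780,56.4328501284988,75.8131246616383,76.9716958691442,36.8585396381833,40.2353697525574,46.6398327478094,40.1872568188063
met08,60.5165521850667,61.8014216522998,56.8446214330718,55.1680261315014,61.0177097007450,58.2466787917443,58.8148098835224,57.0588545963616,30.4034947338173,31.2666612087635,26.5791263627688,26.3102901390926,42.8038369014943,42.0217136620612,51.4737564148669,55.4822485137337,62.0877680432236,61.5936961113672
met09,30.5285994893025,30.3695044172485,38.5332348019296,34.9300443603038,62.2714731878195,63.8346395356703,63.8889994779732,64.4696759171757,44.3253592912764,43.5543774462435,39.4828169653285,30.6202534196696,53.8662262022180,57.2060221416217,69.4287642307185,71.8735359942234,53.8153314465715,54.8793446118120
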