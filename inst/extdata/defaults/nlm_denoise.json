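{"method":"nlm_denoise","entries":[{"signature":[1,100,100,5,5,0,0.1],"times":{"unthreaded":[0.102202177047729,0.095768928527832,0.0920066833496094],"threaded":[0.100822448730469,0.10150671005249,0.112640380859375],"vectorized":[0.14317512512207,0.185116052627563,0.132107973098755]}},{"signature":[1,200,200,5,5,0,0.1],"times":{"unthreaded":[0.399163246154785,0.390588760375977,0.391480922698975],"threaded":[0.403000831604004,0.405510902404785,0.410727977752686],"vectorized":[0.593574047088623,0.397709369659424,0.382183790206909]}},{"signature":[1,100,100,5,10,0,0.1],"times":{"unthreaded":[0.361973524093628,0.35628342628479,0.353124856948853],"threaded":[0.366475820541382,0.392855882644653,0.412916898727417],"vectorized":[0.665884017944336,0.623100519180298,0.462011814117432]}},{"signature":[1,200,200,5,10,0,0.1],"times":{"unthreaded":[1.52596807479858,1.52580666542053,1.57237029075623],"threaded":[1.4690957069397,1.43198823928833,1.47401714324951],"vectorized":[1.62210202217102,1.40536594390869,1.49383282661438]}},{"signature":[1,100,100,7,5,0,0.1],"times":{"unthreaded":[0.177473068237305,0.178967237472534,0.185823917388916],"threaded":[0.18407154083252,0.197628736495972,0.172905921936035],"vectorized":[0.110822916030884,0.127336740493774,0.132967472076416]}},{"signature":[1,200,200,7,5,0,0.1],"times":{"unthreaded":[0.694767713546753,0.683434009552002,0.699426651000977],"threaded":[0.705121517181396,0.699578762054443,0.685418844223022],"vectorized":[0.453360795974731,0.386554718017578,0.416431903839111]}},{"signature":[1,100,100,7,10,0,0.1],"times":{"unthreaded":[0.612327575683594,0.620601177215576,0.615173816680908],"threaded":[0.618499040603638,0.63348126411438,0.655031681060791],"vectorized":[0.455550909042358,0.466206789016724,0.504968404769897]}},{"signature":[1,200,200,7,10,0,0.1],"times":{"unthreaded":[2.61728620529175,2.57731485366821,2.46619439125061],"threaded":[2.48407411575317,2.60080051422119,2.54720425605774],"vectorized":[1.45506978034973,1.40761566162109,1.41067624092102]}},{"signature":[1,100,100,11,5,0,0.1],"times":{"unthreaded":[0.389753580093384,0.394606113433838,0.396481990814209],"threaded":[0.396108627319336,0.400777816772461,0.395249843597412],"vectorized":[0.125603675842285,0.123818159103394,0.131600856781006]}},{"signature":[1,200,200,11,5,0,0.1],"times":{"unthreaded":[1.58535861968994,1.57100605964661,1.53745770454407],"threaded":[1.55206894874573,1.62136769294739,1.5373170375824],"vectorized":[0.366174221038818,0.366345882415771,0.382954835891724]}},{"signature":[1,100,100,11,10,0,0.1],"times":{"unthreaded":[1.40372848510742,1.40455794334412,1.47319483757019],"threaded":[1.60025429725647,1.56799149513245,1.47603392601013],"vectorized":[0.464875936508179,0.477312088012695,0.465286254882812]}},{"signature":[1,200,200,11,10,0,0.1],"times":{"unthreaded":[5.78435063362122,5.7312331199646,5.71828627586365],"threaded":[5.66601181030273,5.9361879825592,5.82488584518433],"vectorized":[1.42069315910339,1.40302968025208,1.45720863342285]}}]}
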