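{"method":"catmull_rom_zoom","entries":[{"signature":[1,10,10,5],"times":{"unthreaded":[0.000876188278198242,0.000306367874145508,0.000255107879638672],"threaded":[0.0102643966674805,0.00921511650085449,0.00747919082641602],"vectorized":[0.00216174125671387,0.00186634063720703,0.00208878517150879]}},{"signature":[10,10,10,5],"times":{"unthreaded":[0.00119924545288086,0.00122594833374023,0.00116634368896484],"threaded":[0.00466394424438477,0.00461769104003906,0.00466799736022949],"vectorized":[0.00223350524902344,0.00210785865783691,0.0020449161529541]}},{"signature":[10,100,100,5],"times":{"unthreaded":[0.121695280075073,0.116684198379517,0.111802577972412],"threaded":[0.153088092803955,0.174501180648804,0.159906625747681],"vectorized":[0.0914614200592041,0.0854964256286621,0.0857894420623779]}},{"signature":[10,300,300,5],"times":{"unthreaded":[2.62307167053223,1.4123113155365,1.60992574691772],"threaded":[1.37239336967468,1.60523176193237,1.39200615882874],"vectorized":[1.09603142738342,0.77408504486084,0.728468656539917]}}]}
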