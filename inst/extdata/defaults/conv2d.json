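{"method":"conv2d","entries":[{"signature":[1,100,100,1],"times":{"unthreaded":[0.000357151031494141,0.00029301643371582,0.000185251235961914],"threaded":[0.0076899528503418,0.00707674026489258,0.0069282054901123],"vectorized":[0.000159978866577148,0.000165700912475586,0.000164031982421875]}},{"signature":[1,500,500,1],"times":{"unthreaded":[0.00359344482421875,0.00370168685913086,0.00367236137390137],"threaded":[0.00990581512451172,0.0110366344451904,0.0124540328979492],"vectorized":[0.00388598442077637,0.00490617752075195,0.00352144241333008]}},{"signature":[1,1000,1000,1],"times":{"unthreaded":[0.0156054496765137,0.0132408142089844,0.0134353637695312],"threaded":[0.0299708843231201,0.0271337032318115,0.0313951969146729],"vectorized":[0.0466554164886475,0.0129573345184326,0.0108394622802734]}},{"signature":[1,100,100,5],"times":{"unthreaded":[0.00109696388244629,0.000710010528564453,0.000754117965698242],"threaded":[0.00689339637756348,0.00688982009887695,0.00745511054992676],"vectorized":[0.000798225402832031,0.000700473785400391,0.000726222991943359]}},{"signature":[1,500,500,5],"times":{"unthreaded":[0.0149075984954834,0.0150456428527832,0.0141160488128662],"threaded":[0.0243778228759766,0.0217759609222412,0.0219657421112061],"vectorized":[0.0216991901397705,0.0154914855957031,0.0179071426391602]}},{"signature":[1,1000,1000,5],"times":{"unthreaded":[0.0653712749481201,0.0589437484741211,0.0649402141571045],"threaded":[0.0810370445251465,0.0803170204162598,0.0762503147125244],"vectorized":[0.132561922073364,0.0753374099731445,0.126463651657104]}},{"signature":[1,100,100,9],"times":{"unthreaded":[0.00224709510803223,0.00211143493652344,0.00208711624145508],"threaded":[0.00876784324645996,0.00785136222839355,0.00783300399780273],"vectorized":[0.00183415412902832,0.00179839134216309,0.00187230110168457]}},{"signature":[1,500,500,9],"times":{"unthreaded":[0.0477139949798584,0.050407886505127,0.0466935634613037],"threaded":[0.055473804473877,0.0567874908447266,0.0544633865356445],"vectorized":[0.0520961284637451,0.047661304473877,0.045325756072998]}},{"signature":[1,1000,1000,9],"times":{"unthreaded":[0.196033477783203,0.208033561706543,0.195414543151855],"threaded":[0.21503472328186,0.255940675735474,0.298134565353394],"vectorized":[0.249339818954468,0.228688478469849,0.23876428604126]}},{"signature":[1,100,100,13],"times":{"unthreaded":[0.00426745414733887,0.00426602363586426,0.00426816940307617],"threaded":[0.0115373134613037,0.0111169815063477,0.0123305320739746],"vectorized":[0.00542688369750977,0.00366306304931641,0.00446820259094238]}},{"signature":[1,500,500,13],"times":{"unthreaded":[0.114979982376099,0.115691423416138,0.110312461853027],"threaded":[0.115230321884155,0.115464210510254,0.114333868026733],"vectorized":[0.106560230255127,0.146478414535522,0.0953733921051025]}},{"signature":[1,1000,1000,13],"times":{"unthreaded":[0.42567253112793,0.425778865814209,0.442025184631348],"threaded":[0.45257306098938,0.462475538253784,0.434634923934937],"vectorized":[0.572401285171509,0.509618282318115,0.529210329055786]}},{"signature":[1,100,100,17],"times":{"unthreaded":[0.00722265243530273,0.0070805549621582,0.00703930854797363],"threaded":[0.0134336948394775,0.0130300521850586,0.0127556324005127],"vectorized":[0.00796270370483398,0.00770163536071777,0.00642180442810059]}},{"signature":[1,500,500,17],"times":{"unthreaded":[0.17946982383728,0.197189569473267,0.201790571212769],"threaded":[0.208812236785889,0.191567897796631,0.204192638397217],"vectorized":[0.215145826339722,0.172179460525513,0.175445079803467]}},{"signature":[1,1000,1000,17],"times":{"unthreaded":[0.746559143066406,0.731391429901123,0.777777194976807],"threaded":[0.778702259063721,0.754224061965942,0.74617338180542],"vectorized":[0.803226470947266,0.772992610931396,0.782320737838745]}},{"signature":[1,100,100,21],"times":{"unthreaded":[0.0108864307403564,0.0115106105804443,0.0122265815734863],"threaded":[0.0233933925628662,0.019481897354126,0.0182125568389893],"vectorized":[0.0107874870300293,0.00994372367858887,0.01065993309021]}},{"signature":[1,500,500,21],"times":{"unthreaded":[0.286713361740112,0.288776159286499,0.296413898468018],"threaded":[0.295498371124268,0.287706136703491,0.300786256790161],"vectorized":[0.261899709701538,0.279056072235107,0.253213167190552]}},{"signature":[1,1000,1000,21],"times":{"unthreaded":[1.1587929725647,1.11691451072693,1.18326497077942],"threaded":[1.1702287197113,1.14516019821167,1.23460125923157],"vectorized":[1.41875529289246,1.3259916305542,1.40133666992188]}}]}
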