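1.523585398772156818e+00
-5.199920531202478102e+00
3.752255979032286248e+00
4.702823581956069532e+00
-9.755175943269181360e+00
-6.510897534311590462e+00
6.392020158364268845e-01
-1.581212961717910925e+00
-8.400578752144396977e-02
-4.265219637867899927e+00
4.396989874314142455e+00
3.888959677144741445e+00
3.301534878060802258e-01
5.636206034840164136e+00
2.337546711260228172e+00
-4.296462314416190864e+00
1.843753920412494196e+00
-4.794413004144994161e+00
4.392251506536362982e+00
-2.496295549312644857e-01
-9.243118177263027757e-01
-3.404647722019706890e+00
6.112706693370151712e+00
-7.726474103440107433e-01
-2.141639110815535929e+00
-1.760667752441147815e+00
2.661545927766743702e+00
1.827220321820391735e+00
2.063663057979941762e+00
2.154105015039413651e+00
1.070823800435230666e+01
-2.032075081923077953e+00
-2.561213645357686808e+00
-4.068863641239389040e+00
3.079897112877478360e+00
5.644861463604458507e+00
-5.697372882743754197e-01
-4.200782384812640657e+00
-4.122406078456197775e+00
3.252963939123505455e+00
3.716270856017211521e+00
2.715771341525974769e+00
-3.327548536443471594e+00
1.160806615333598746e+00
5.834290457036410693e-01
1.093442983645064759e+00
4.357143889740949128e+00
1.117977743873411312e+00
3.394567815359474494e+00
3.378953474444573168e-01
1.445596993449920653e+00
3.156441129192701922e+00
-7.285779099278332005e+00
-1.598356081786506788e+00
-2.351863271463977334e+00
-3.194389241216709863e+00
-1.375711256133418603e+00
7.474706556171978988e+00
-4.329155578466216348e+00
4.841391772957404527e+00
-8.414348858079023330e+00
-1.674425149928874257e+00
8.137653255250278939e-01
2.931111656796390630e+00
3.556132898964274869e+00
3.966736175999626024e+00
-1.743625361242187921e+00
-2.311758963322835925e+00
4.289879406285769470e+00
-9.565216244080744223e-01
-6.378431616689609562e+00
-5.666436070017403459e+00
-4.597261430008056315e+00
2.485803720268820349e+00
7.121286803528261711e-01
3.452426770338841155e+00
-2.136263231682671293e+00
7.926984553835711989e-01
3.127951969836683777e+00
-1.546732698601192002e+00
2.283876187787057255e+00
-3.309629705333256400e+00
-1.815269232825358792e+00
-1.908689469991645460e+00
-5.979198227945198063e+00
2.434862403927909202e+00
-2.347011701013619334e+00
6.247059363843714824e-02
2.403733294529544651e+00
2.232655880149720495e+00
3.326925544863930995e+00
-4.924274225471180766e-01
-2.116491560220768786e+00
-3.985910545319952814e-01
-8.436672169790149667e+00
-7.235562362115436130e+00
-6.613498061772011383e+00
-4.986234138007408667e+00
1.998871133617182938e+00
-4.527395276800303847e+00
-1.890812770196948378e+00
6.496141488930327057e+00
-1.781319855307129663e+00
3.687577842335432621e+00
-4.668088400049384745e+00
-1.027187789338150026e+00
-4.750110274552906020e+00
-1.695165379502812320e+00
4.201540687286977160e+00
-8.636602115961743209e+00
2.172118217729286815e+00
1.188678011661389533e+00
-2.970749778483972037e+00
-7.230289271942273110e+00
3.606475385693475588e-01
-2.647463545319012290e+00
1.163381056773519884e+00
1.092607276172143926e-01
8.008894456604577883e+00
-1.196778137365121397e+00
-5.117487463109324786e+00
8.963781747815807721e-01
1.099983419858825862e+00
6.795937876202183148e+00
4.175556229572892519e+00
1.784355295747546588e+00
7.316514456097809038e+00
-5.943815271614254492e+00
-3.198757663748738711e+00
-4.632879707027624860e+00
-1.949049015778839822e+00
-6.883430737781544018e+00
3.175754734072021357e+00
-1.111113485493866904e+00
-7.354031472513289813e+00
-5.077895406037708170e+00
1.567569237250976411e+00
4.190632839471905235e+00
9.983654458458932623e+00
1.456931233003664872e+01
2.072047166379981764e+00
-4.947690600159321050e+00
-1.066023140365654598e+01
1.338557311719179133e+00
-4.064705476551630170e+00
-2.076786300898426418e+00
-3.060483995299040139e+00
-7.039544320819263179e-01
5.329901153938218172e+00
7.852428372267230561e-01
-7.931741851934415166e-01
-5.178268764129057899e+00
-8.373414723521785064e+00
-2.431539545366654398e+00
-2.689127540916024794e-01
8.839649567899414251e+00
6.513726073644292569e-01
4.913697555115287940e+00
-2.496477992695760317e+00
-5.924718832085122955e+00
-4.825583811161859416e+00
-3.626130322678766227e+00
1.064234866217582187e+01
-4.106933396121930535e+00
4.192446018681724951e+00
-4.514635890435132026e+00
4.657865064371220498e+00
1.924754830529315841e+00
-7.831894882904520960e-01
-2.038126306771701202e-01
-3.273938477146951964e+00
2.230361007410402774e+00
-2.274917401703900222e+00
-6.128028818836241065e+00
-6.389687871598096258e+00
8.629395886105973856e-01
7.895456282052174757e+00
7.999580678671912581e-01
-5.931916305494128183e-01
1.429130698012714529e+00
6.530008708534124295e+00
1.096912506819281763e+00
-2.054636154168685724e+00
5.531443550299444567e+00
2.143782192308067547e+00
7.678779959979959990e+00
9.161721861095306618e-01
-6.122345158602501058e+00
-6.840795996228324682e+00
8.254639661156247143e+00
8.618328603916484809e+00
-8.975960664130032685e-01
-1.915936605679938731e+00
7.307221461211010904e+00
-5.535228410217439610e+00
-4.473635094779131904e+00
3.216633973445222061e+00
-1.973025614297947872e+00
-2.560933360035648129e-02
-8.172144926225628492e-01
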