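1.009491391042661029e-01
9.271740879465316387e-02
2.158234734127523480e-01
4.759036846634556173e-01
1.758870019703978049e-01
1.312040876782515575e+00
7.738374215077741258e-01
5.114240987859850485e+00
3.413763788326375170e+00
7.172769469361548467e-01
6.363063917737478148e-01
1.197338550855175099e-01
1.648827112564899444e+00
3.526386850884542401e+00
6.585951024300227274e-01
1.580001279420854221e+00
2.090807020337986932e-02
7.387497243206925468e+00
1.061797541415692991e-01
1.511873779835005260e+00
5.450053723919860704e-02
3.436776803197564290e-01
4.010851746654314764e-01
1.058372925658795261e+00
6.658805526835244459e-02
4.495495569673912950e-01
2.424817972692262236e-01
1.214770755044403128e-01
1.684310668713472348e+00
4.810531922963129925e-01
9.803101949326702147e-02
5.730674793876915363e-01
1.959062118466847191e-01
1.104845800949253451e-03
1.100494119477407468e-01
1.195152004315845673e+00
1.736182709627909129e-03
4.772821228521001435e-01
7.004496130916131325e-01
2.985756182980069950e-01
8.048646424148326872e-01
1.827402224153801491e+00
6.259158847687485983e-01
5.873030373434313667e-01
1.516476711815944456e-01
6.316855185327808764e-01
2.319150898786694892e+00
5.830359787072295630e-01
7.289844249422187117e-01
2.876447600222137080e+00
3.996410745643562135e-01
4.509769226189196123e-02
2.100988245919115815e+00
6.911265354644027248e-01
1.429185491339364233e-01
8.775722244160109875e-02
6.679382330150003266e-01
1.569528914827082344e+00
3.104016865802530778e-02
7.280866110344341724e-02
1.116453912416248001e-01
1.699464939322498092e-01
9.975215766130063333e-01
5.649287720012371311e-02
1.908083623227857739e+00
2.518506809003173252e+00
4.996501216169815685e+00
9.796575092182463126e-03
2.164643004203060384e-01
7.342285508396904081e-01
6.990547826754296701e-02
4.114415672325533180e+00
3.356146786781740055e+00
6.837042581339856095e-01
1.997870009775918110e+00
2.072206387901075253e+00
7.551356906558370774e-01
4.887682575133336371e-01
2.006799243086612172e+00
5.984922093403856058e-01
2.482668143965053531e+00
1.010975149850649624e+00
6.845609640059754364e-01
5.000068485623454517e-01
3.424655903682320424e-01
2.205566458747367509e-01
1.063310491089649798e-02
3.105730777488991401e-01
1.828425400777984947e-02
2.502957401631655254e-01
3.306645264615720059e+00
2.473247731011129158e+00
2.404114099101026358e+00
4.003782637299134750e-01
2.983477860659324854e+00
1.149228849915702844e+00
4.491575798474017889e-02
2.623603033555176878e-01
1.081284648775456603e+00
1.772135543815329117e-01
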