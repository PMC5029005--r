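# Small plant-name lexicon covering the surface forms used in the packaged
# worked examples and the synthetic-sentence templates.
Pomegranate	NA
Punica granatum	Taxonomy:22663
corn	Taxonomy:4577
ginger	Taxonomy:94328
switchgrass	Taxonomy:38727
Panax notoginseng	Taxonomy:44586
Panax	Taxonomy:4053
black soybean	NA
soybean	Taxonomy:3847
soybean oil	NA
Feverfew	Taxonomy:99611
marijuana	Taxonomy:3483
Haematococcus pluvialis	Taxonomy:44745
papaya	Taxonomy:3649
rice	Taxonomy:4530
rice straw	NA
tobacco	Taxonomy:4097
potato	Taxonomy:4113
masson pine	Taxonomy:88730
Pinus massoniana	Taxonomy:88730
aloe	Taxonomy:84484
tomato	Taxonomy:4081
kiwifruit	Taxonomy:3625
Ginkgo biloba	Taxonomy:3311
cucumber	Taxonomy:3659
Cimicifuga racemosa	Taxonomy:111091
Cruciferae	Taxonomy:3700
liverwort	Taxonomy:3195
Marchantia polymorpha	Taxonomy:3197
Pisum sativum	Taxonomy:3888
snapdragon	Taxonomy:4151
blackberries	Taxonomy:32247
blueberries	Taxonomy:13749
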