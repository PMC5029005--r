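# Small chemical-name lexicon covering the surface forms used in the
# packaged worked examples and the synthetic-sentence templates.
anthocyanins	MeSH:D000872
anthocyanin	MeSH:D000872
FB1	CAS:116355-83-0
sesquiterpenes	MeSH:D012717
carbon	MeSH:D002244
saponins	MeSH:D012503
Saponins	MeSH:D012503
parthenolide	CAS:20554-84-1
fatty acids	MeSH:D005227
Delta9-tetrahydrocannabinol	MeSH:D013759
astaxanthin	CAS:472-61-7
calcium	MeSH:D002118
nitrogen	MeSH:D009584
ammonia	MeSH:D000641
nitrosamines	MeSH:D009602
dichloromethane	CAS:75-09-2
emodin	CAS:518-82-1
actinidin	CAS:39279-27-1
bilobalide	CAS:33570-04-6
methyl bromide	CAS:74-83-9
isopropanol	CAS:67-63-0
methanol	CAS:67-56-1
ethanol	CAS:64-17-5
chloroform	CAS:67-66-3
3-(methylthio)propanal	CAS:3268-49-3
Allyl isothiocyanate	CAS:57-06-7
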