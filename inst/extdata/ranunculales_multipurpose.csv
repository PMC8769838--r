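species,family,n_categories
Aconitum carmichaelili,Ranunculaceae,13
Aconitum flavum,Ranunculaceae,10
Aconitum kusnezoffii,Ranunculaceae,10
Aconitum naviculare,Ranunculaceae,11
Aconitum scaposum,Ranunculaceae,13
Anemone hupehensis,Ranunculaceae,10
Anemone rivularis,Ranunculaceae,12
Anemone rivularis var. flore-minore,Ranunculaceae,10
Anemone vitifolia,Ranunculaceae,11
Clematis armandii,Ranunculaceae,12
Clematis chinensis,Ranunculaceae,12
Clematis hexapetala,Ranunculaceae,12
Clematis manshurica,Ranunculaceae,12
Coptis chinensis,Ranunculaceae,12
Coptis chinensis var. brevisepala,Ranunculaceae,12
Coptis deltoidea,Ranunculaceae,12
Coptis omeiensis,Ranunculaceae,12
Coptis quinquesecta,Ranunculaceae,12
Coptis teeta,Ranunculaceae,12
Nigella glandulifera,Ranunculaceae,10
Nigella glandulifera,Ranunculaceae,10
Ranunculus japonicus,Ranunculaceae,10
Semiaquilegia adoxoides,Ranunculaceae,12
Thalictrum acutifolium,Ranunculaceae,10
Thalictrum alpinum var. elatum,Ranunculaceae,12
Thalictrum cultratum,Ranunculaceae,11
Thalictrum delavayi,Ranunculaceae,11
Thalictrum foliolosum,Ranunculaceae,11
Thalictrum ramosum,Ranunculaceae,11
Thalictrum reticulatum,Ranunculaceae,11
Thalictrum trichopus,Ranunculaceae,11
Berberis amurensis,Berberidaceae,12
Berberis dasystachya,Berberidaceae,10
Berberis diaphana,Berberidaceae,12
Berberis heteropoda,Berberidaceae,10
Berberis jamesiana,Berberidaceae,10
Berberis julianae,Berberidaceae,11
Berberis poiretii,Berberidaceae,13
Berberis pruinose,Berberidaceae,10
Berberis vernae,Berberidaceae,13
Berberis vulgaris,Berberidaceae,11
Berberis wilsoniae,Berberidaceae,12
Epimedium acuminatum,Berberidaceae,10
Epimedium sagittatum,Berberidaceae,10
Mahonia bealei,Berberidaceae,14
Mahonia eurybracteata,Berberidaceae,15
Mahonia fortune,Berberidaceae,14
Mahonia gracilipes,Berberidaceae,14
Arcangelisia gusanlung,Menispermaceae,11
Cyclea hypoglauca,Menispermaceae,10
Stephania cepharantha,Menispermaceae,11
Stephania hernandiifolia,Menispermaceae,10
Stephania kuinanensis,Menispermaceae,10
Stephania kwangsiensis,Menispermaceae,11
Stephania kwangsiensis,Menispermaceae,11
Stephania micrantha,Menispermaceae,10
Stephania tetrandra,Menispermaceae,10
Tinospora capillipes,Menispermaceae,13
Tinospora crispa,Menispermaceae,10
Tinospora sagittate,Menispermaceae,13
Tinospora sinensis,Menispermaceae,13
Akebia trifoliata,Lardizabalaceae,10
Akebia trifoliata var. australis,Lardizabalaceae,11
Sargentodoxa cuneata,Lardizabalaceae,10
Corydalis edulis,Papaveraceae,10
Eomecon chionantha,Papaveraceae,10
Macleaya cordata,Papaveraceae,10
Macleaya microcarpa,Papaveraceae,10
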