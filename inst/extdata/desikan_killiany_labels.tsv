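label	hemisphere	cortical
ctx-lh-superiorfrontal	L	TRUE
ctx-lh-rostralmiddlefrontal	L	TRUE
ctx-lh-caudalmiddlefrontal	L	TRUE
ctx-lh-parsopercularis	L	TRUE
ctx-lh-parstriangularis	L	TRUE
ctx-lh-parsorbitalis	L	TRUE
ctx-lh-lateralorbitofrontal	L	TRUE
ctx-lh-medialorbitofrontal	L	TRUE
ctx-lh-precentral	L	TRUE
ctx-lh-paracentral	L	TRUE
ctx-lh-postcentral	L	TRUE
ctx-lh-supramarginal	L	TRUE
ctx-lh-superiorparietal	L	TRUE
ctx-lh-inferiorparietal	L	TRUE
ctx-lh-precuneus	L	TRUE
ctx-lh-cuneus	L	TRUE
ctx-lh-pericalcarine	L	TRUE
ctx-lh-lateraloccipital	L	TRUE
ctx-lh-lingual	L	TRUE
ctx-lh-fusiform	L	TRUE
ctx-lh-parahippocampal	L	TRUE
ctx-lh-superiortemporal	L	TRUE
ctx-lh-middletemporal	L	TRUE
ctx-lh-inferiortemporal	L	TRUE
ctx-lh-transversetemporal	L	TRUE
ctx-lh-insula	L	TRUE
ctx-lh-caudalanteriorcingulate	L	TRUE
ctx-lh-rostralanteriorcingulate	L	TRUE
ctx-lh-posteriorcingulate	L	TRUE
ctx-lh-isthmuscingulate	L	TRUE
ctx-rh-superiorfrontal	R	TRUE
ctx-rh-rostralmiddlefrontal	R	TRUE
ctx-rh-caudalmiddlefrontal	R	TRUE
ctx-rh-parsopercularis	R	TRUE
ctx-rh-parstriangularis	R	TRUE
ctx-rh-parsorbitalis	R	TRUE
ctx-rh-lateralorbitofrontal	R	TRUE
ctx-rh-medialorbitofrontal	R	TRUE
ctx-rh-precentral	R	TRUE
ctx-rh-paracentral	R	TRUE
ctx-rh-postcentral	R	TRUE
ctx-rh-supramarginal	R	TRUE
ctx-rh-superiorparietal	R	TRUE
ctx-rh-inferiorparietal	R	TRUE
ctx-rh-precuneus	R	TRUE
ctx-rh-cuneus	R	TRUE
ctx-rh-pericalcarine	R	TRUE
ctx-rh-lateraloccipital	R	TRUE
ctx-rh-lingual	R	TRUE
ctx-rh-fusiform	R	TRUE
ctx-rh-parahippocampal	R	TRUE
ctx-rh-superiortemporal	R	TRUE
ctx-rh-middletemporal	R	TRUE
ctx-rh-inferiortemporal	R	TRUE
ctx-rh-transversetemporal	R	TRUE
ctx-rh-insula	R	TRUE
ctx-rh-caudalanteriorcingulate	R	TRUE
ctx-rh-rostralanteriorcingulate	R	TRUE
ctx-rh-posteriorcingulate	R	TRUE
ctx-rh-isthmuscingulate	R	TRUE
left-thalamus	L	FALSE
left-caudate	L	FALSE
left-putamen	L	FALSE
left-pallidum	L	FALSE
left-hippocampus	L	FALSE
left-amygdala	L	FALSE
left-accumbens	L	FALSE
right-thalamus	R	FALSE
right-caudate	R	FALSE
right-putamen	R	FALSE
right-pallidum	R	FALSE
right-hippocampus	R	FALSE
right-amygdala	R	FALSE
right-accumbens	R	FALSE
brainstem	M	FALSE
corpuscallosum	M	FALSE
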