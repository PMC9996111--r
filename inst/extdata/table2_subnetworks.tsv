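region_a	region_b	t_drs	t_crsr
right caudal middle frontal	left superior frontal	3.72	NA
left pars opercularis	left superior frontal	4.09	NA
left rostral middle frontal	left superior frontal	4.18	NA
right caudal middle frontal	left caudal middle frontal	3.63	NA
left rostral middle frontal	left caudal middle frontal	3.70	NA
right superior frontal	left precentral	3.67	NA
right caudal middle frontal	left precentral	3.60	NA
right paracentral	left precentral	3.62	NA
left rostral middle frontal	left precentral	3.67	NA
left superior frontal	left precentral	4.13	NA
left caudal middle frontal	left precentral	3.66	NA
left precentral	left postcentral	4.04	NA
right precuneus	left supramarginal	3.56	NA
right isthmus cingulate	left superior parietal	3.84	NA
right superior parietal	left superior parietal	3.88	NA
right precuneus	left superior parietal	3.77	NA
left superior frontal	left superior parietal	3.60	NA
left postcentral	left superior parietal	3.73	NA
right isthmus cingulate	left inferior parietal	3.69	NA
right precuneus	left inferior parietal	3.51	NA
left superior parietal	left lateral occipital	3.57	NA
right isthmus cingulate	left inferior temporal	3.56	NA
left superior frontal	left insula	3.90	NA
left precentral	left insula	3.74	NA
left postcentral	left insula	3.67	NA
right inferior parietal	left thalamus (Pul)	3.53	NA
right precuneus	left thalamus (Pul)	3.65	NA
left precentral	left thalamus (MD)	3.54	3.53
left precentral	left thalamus (LP-VP)	3.72	3.68
left precentral	left thalamus (PuM)	3.53	3.54
left precentral	left thalamus (VP-VL)	3.58	3.56
left precentral	left caudate	3.65	NA
right isthmus cingulate	left putamen	3.77	NA
right inferior parietal	left putamen	3.60	NA
right precuneus	left putamen	3.70	NA
right lateral occipital	left putamen	3.57	NA
left superior frontal	left putamen	3.85	NA
left precentral	left putamen	3.78	NA
left postcentral	left putamen	3.71	NA
left precentral	left pallidum	3.66	NA
left precentral	brain stem	3.54	NA
left postcentral	left thalamus (LP-VP)	NA	3.73
left postcentral	left thalamus (VL)	NA	3.51
left supramarginal	left thalamus (VL)	NA	3.53
left postcentral	left thalamus (VP-VL)	NA	3.55
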