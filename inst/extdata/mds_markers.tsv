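marker_id	lr_present	lr_absent	assessable	concept_ids
rbd_polysomnographic	130	0.62	TRUE	C_RBD
possible_rbd_screen	2.3	0.76	TRUE	C_RBD_SCREEN
olfactory_loss	4.0	0.43	FALSE
constipation	2.2	0.8	TRUE	C_CONSTIPATION
daytime_somnolence	2.2	0.88	TRUE	C_SOMNOLENCE
orthostatic_hypotension	3.2	0.8	TRUE	C_ORTHOSTATIC
erectile_dysfunction	3.4	0.87	TRUE	C_ERECTILE
urinary_dysfunction	1.9	0.9	TRUE	C_URINARY
depression	1.8	0.85	TRUE	C_DEPRESSION
subthreshold_parkinsonism	10	0.7	FALSE
dat_imaging_deficit	43.3	0.66	FALSE
pesticide_exposure	1.5	1.0	FALSE
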