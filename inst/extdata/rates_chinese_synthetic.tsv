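population	age_start	age_end	h1	h2	one_minus_AR
Chinese	20	25	0.0000070	0.00035	0.4751981
Chinese	25	30	0.0000350	0.00045	0.4751981
Chinese	30	35	0.0001500	0.00060	0.4751981
Chinese	35	40	0.0003500	0.00085	0.4751981
Chinese	40	45	0.0007000	0.00120	0.4751981
Chinese	45	50	0.0009500	0.00180	0.4751981
Chinese	50	55	0.0010000	0.00280	0.5031640
Chinese	55	60	0.0009500	0.00440	0.5031640
Chinese	60	65	0.0009000	0.00700	0.5031640
Chinese	65	70	0.0008500	0.01150	0.5031640
Chinese	70	75	0.0008000	0.01900	0.5031640
Chinese	75	80	0.0007500	0.03300	0.5031640
Chinese	80	85	0.0007000	0.05800	0.5031640
Chinese	85	90	0.0006500	0.10500	0.5031640
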