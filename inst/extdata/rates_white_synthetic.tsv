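population	age_start	age_end	h1	h2	one_minus_AR
White	20	25	0.0000160	0.00044	0.5788413
White	25	30	0.0000780	0.00053	0.5788413
White	30	35	0.0002400	0.00068	0.5788413
White	35	40	0.0005800	0.00090	0.5788413
White	40	45	0.0011700	0.00125	0.5788413
White	45	50	0.0018700	0.00190	0.5788413
White	50	55	0.0022200	0.00292	0.5788413
White	55	60	0.0026600	0.00450	0.5788413
White	60	65	0.0033000	0.00700	0.5788413
White	65	70	0.0039200	0.01100	0.5788413
White	70	75	0.0042100	0.01800	0.5788413
White	75	80	0.0046100	0.03000	0.5788413
White	80	85	0.0045000	0.05200	0.5788413
White	85	90	0.0042000	0.09600	0.5788413
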