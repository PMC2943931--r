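label	x	y
E01	0	0
E02	0	0.2
E03	-0.1732	0.1
E04	-0.1732	-0.1
E05	0	-0.2
E06	0.1732	-0.1
E07	0.1732	0.1
E08	0	0.4
E09	-0.2	0.3464
E10	-0.3464	0.2
E11	-0.4	0
E12	-0.3464	-0.2
E13	-0.2	-0.3464
E14	0	-0.4
E15	0.2	-0.3464
E16	0.3464	-0.2
E17	0.4	0
E18	0.3464	0.2
E19	0.2	0.3464
E20	0	0.6
E21	-0.2052	0.5638
E22	-0.3857	0.4596
E23	-0.5196	0.3
E24	-0.5909	0.1042
E25	-0.5909	-0.1042
E26	-0.5196	-0.3
E27	-0.3857	-0.4596
E28	-0.2052	-0.5638
E29	0	-0.6
E30	0.2052	-0.5638
E31	0.3857	-0.4596
E32	0.5196	-0.3
E33	0.5909	-0.1042
E34	0.5909	0.1042
E35	0.5196	0.3
E36	0.3857	0.4596
E37	0.2052	0.5638
E38	0	0.8
E39	-0.2071	0.7727
E40	-0.4	0.6928
E41	-0.5657	0.5657
E42	-0.6928	0.4
E43	-0.7727	0.2071
E44	-0.8	0
E45	-0.7727	-0.2071
E46	-0.6928	-0.4
E47	-0.5657	-0.5657
E48	-0.4	-0.6928
E49	-0.2071	-0.7727
E50	0	-0.8
E51	0.2071	-0.7727
E52	0.4	-0.6928
E53	0.5657	-0.5657
E54	0.6928	-0.4
E55	0.7727	-0.2071
E56	0.8	0
E57	0.7727	0.2071
E58	0.6928	0.4
E59	0.5657	0.5657
E60	0.4	0.6928
E61	0.2071	0.7727
E62	0	1
E63	-0.2013	0.9795
E64	-0.3944	0.919
E65	-0.5713	0.8208
E66	-0.7248	0.689
E67	-0.8486	0.529
E68	-0.9378	0.3473
E69	-0.9885	0.1514
E70	-0.9987	-0.0506
E71	-0.9681	-0.2507
E72	-0.8978	-0.4404
E73	-0.7908	-0.6121
E74	-0.6514	-0.7588
E75	-0.4853	-0.8743
E76	-0.2994	-0.9541
E77	-0.1012	-0.9949
E78	0.1012	-0.9949
E79	0.2994	-0.9541
E80	0.4853	-0.8743
E81	0.6514	-0.7588
E82	0.7908	-0.6121
E83	0.8978	-0.4404
E84	0.9681	-0.2507
E85	0.9987	-0.0506
E86	0.9885	0.1514
E87	0.9378	0.3473
E88	0.8486	0.529
E89	0.7248	0.689
E90	0.5713	0.8208
E91	0.3944	0.919
E92	0.2013	0.9795
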