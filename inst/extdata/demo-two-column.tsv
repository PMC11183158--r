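ID	Set
e02	S1
e03	S1
e07	S1
e08	S1
e10	S1
e11	S1
e13	S1
e14	S1
e15	S1
e18	S1
e19	S1
e20	S1
e22	S1
e24	S1
e25	S1
e26	S1
e29	S1
e30	S1
e34	S1
e35	S1
e39	S1
e40	S1
e01	S2
e04	S2
e06	S2
e07	S2
e08	S2
e12	S2
e13	S2
e14	S2
e15	S2
e16	S2
e18	S2
e21	S2
e22	S2
e24	S2
e26	S2
e27	S2
e28	S2
e29	S2
e30	S2
e31	S2
e34	S2
e36	S2
e38	S2
e39	S2
e01	S3
e02	S3
e05	S3
e06	S3
e07	S3
e08	S3
e09	S3
e11	S3
e12	S3
e13	S3
e14	S3
e15	S3
e17	S3
e18	S3
e20	S3
e22	S3
e23	S3
e24	S3
e26	S3
e29	S3
e30	S3
e32	S3
e33	S3
e34	S3
e37	S3
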