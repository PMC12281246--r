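set_name	pt_code	pt_label	status
seizures	91000001	Synthetic seizure PT 01	include
seizures	91000002	Synthetic seizure PT 02	include
seizures	91000003	Synthetic seizure PT 03	include
seizures	91000004	Synthetic seizure PT 04	include
seizures	91000005	Synthetic seizure PT 05	include
seizures	91000006	Synthetic seizure PT 06	include
seizures	91000007	Synthetic seizure PT 07	include
seizures	91000008	Synthetic seizure PT 08	include
seizures	91000009	Synthetic seizure PT 09	include
seizures	91000010	Synthetic seizure PT 10	include
seizures	91000011	Synthetic seizure PT 11	include
seizures	91000012	Synthetic seizure PT 12	include
seizures	91000013	Synthetic seizure PT 13	include
seizures	91000014	Synthetic seizure PT 14	include
seizures	91000015	Synthetic seizure PT 15	include
seizures	91000016	Synthetic seizure PT 16	include
seizures	91000017	Synthetic seizure PT 17	include
seizures	91000018	Synthetic seizure PT 18	include
seizures	91000019	Synthetic seizure PT 19	include
seizures	91000020	Synthetic seizure PT 20	include
seizures	91000021	Synthetic seizure PT 21	include
seizures	91000022	Synthetic seizure PT 22	include
seizures	91000023	Synthetic seizure PT 23	include
seizures	91000024	Synthetic seizure PT 24	include
seizures	91000025	Synthetic seizure PT 25	include
seizures	91000026	Synthetic seizure PT 26	include
seizures	91000027	Synthetic seizure PT 27	include
seizures	91000028	Synthetic seizure PT 28	include
seizures	91000029	Synthetic seizure PT 29	include
seizures	91000030	Synthetic seizure PT 30	include
seizures	91000031	Synthetic seizure PT 31	include
seizures	91000032	Synthetic seizure PT 32	include
seizures	91000033	Synthetic seizure PT 33	include
seizures	91000034	Synthetic seizure PT 34	include
seizures	91000035	Synthetic seizure PT 35	include
seizures	91000036	Synthetic seizure PT 36	include
seizures	91000037	Synthetic seizure PT 37	include
seizures	91000038	Synthetic seizure PT 38	include
seizures	91000039	Synthetic seizure PT 39	include
seizures	91000040	Synthetic seizure PT 40	include
seizures	91000041	Synthetic seizure PT 41	include
seizures	91100001	Synthetic excluded seizure PT 01	exclude
seizures	91100002	Synthetic excluded seizure PT 02	exclude
seizures	91100003	Synthetic excluded seizure PT 03	exclude
seizures	91100004	Synthetic excluded seizure PT 04	exclude
seizures	91100005	Synthetic excluded seizure PT 05	exclude
seizures	91100006	Synthetic excluded seizure PT 06	exclude
seizures	91100007	Synthetic excluded seizure PT 07	exclude
seizures	91100008	Synthetic excluded seizure PT 08	exclude
seizures	91100009	Synthetic excluded seizure PT 09	exclude
seizures	91100010	Synthetic excluded seizure PT 10	exclude
seizures	91100011	Synthetic excluded seizure PT 11	exclude
seizures	91100012	Synthetic excluded seizure PT 12	exclude
seizures	91100013	Synthetic excluded seizure PT 13	exclude
seizures	91100014	Synthetic excluded seizure PT 14	exclude
seizures	91100015	Synthetic excluded seizure PT 15	exclude
seizures	91100016	Synthetic excluded seizure PT 16	exclude
seizures	91100017	Synthetic excluded seizure PT 17	exclude
seizures	91100018	Synthetic excluded seizure PT 18	exclude
seizures	91100019	Synthetic excluded seizure PT 19	exclude
seizures	91100020	Synthetic excluded seizure PT 20	exclude
seizures	91100021	Synthetic excluded seizure PT 21	exclude
seizures	91100022	Synthetic excluded seizure PT 22	exclude
seizures	91100023	Synthetic excluded seizure PT 23	exclude
seizures	91100024	Synthetic excluded seizure PT 24	exclude
seizures	91100025	Synthetic excluded seizure PT 25	exclude
seizures	91100026	Synthetic excluded seizure PT 26	exclude
seizures	91100027	Synthetic excluded seizure PT 27	exclude
seizures	91100028	Synthetic excluded seizure PT 28	exclude
seizures	91100029	Synthetic excluded seizure PT 29	exclude
seizures	91100030	Synthetic excluded seizure PT 30	exclude
seizures	91100031	Synthetic excluded seizure PT 31	exclude
seizures	91100032	Synthetic excluded seizure PT 32	exclude
seizures	91100033	Synthetic excluded seizure PT 33	exclude
seizures	91100034	Synthetic excluded seizure PT 34	exclude
seizures	91100035	Synthetic excluded seizure PT 35	exclude
seizures	91100036	Synthetic excluded seizure PT 36	exclude
seizures	91100037	Synthetic excluded seizure PT 37	exclude
seizures	91100038	Synthetic excluded seizure PT 38	exclude
seizures	91100039	Synthetic excluded seizure PT 39	exclude
seizures	91100040	Synthetic excluded seizure PT 40	exclude
seizures	91100041	Synthetic excluded seizure PT 41	exclude
seizures	10076981	Post-stroke seizure	exclude
seizures	10036312	Post-traumatic epilepsy	exclude
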