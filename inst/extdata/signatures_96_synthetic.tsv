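context	SBS5_like	SBS18_like	SBS44_like	scE_like	scF_like
A[C>A]A	0.00816844	0.05846132	0.00239327	0.00179463	0
A[C>A]C	0.00906374	0.05072112	0.00244982	0.00283688	0
A[C>A]G	0.00601292	0.04240306	0.00151468	0.0019862	0
A[C>A]T	0.00745889	0.04994958	0.00208958	0.00128641	0
C[C>A]A	0.00732057	0.03482447	0.00307811	0.00222769	0
C[C>A]C	0.01110738	0.09981677	0.00213423	0.00254708	0
C[C>A]G	0.00861377	0.04162662	0.0022209	0.00212388	0
C[C>A]T	0.00681444	0.09158072	0.00157344	0.00095233	0
G[C>A]A	0.01068566	0.04149188	0.00203198	0.00133382	0
G[C>A]C	0.00848022	0.05053863	0.00177332	0.0023671	0
G[C>A]G	0.00930632	0.04002279	0.00250706	0.00191062	0
G[C>A]T	0.00841286	0.06352699	0.00276123	0.00190426	0
T[C>A]A	0.00655931	0.03636029	0.00272466	0.00166967	0
T[C>A]C	0.00836196	0.04463417	0.002465	0.00117014	0
T[C>A]G	0.00616473	0.06510287	0.00169758	0.0018605	0
T[C>A]T	0.01023241	0.04471798	0.00263041	0.00251806	0
A[C>G]A	0.0075804	0.00153396	0.00247597	0.00246656	0
A[C>G]C	0.00830427	0.00216248	0.0030115	0.00220334	0
A[C>G]G	0.00431606	0.00269841	0.00317082	0.00112139	0
A[C>G]T	0.00723954	0.00131304	0.0018235	0.00185653	0
C[C>G]A	0.0067778	0.00103665	0.00218499	0.00198862	0
C[C>G]C	0.01009903	0.00141917	0.00256404	0.00188596	0
C[C>G]G	0.00677557	0.00154774	0.00257719	0.00124336	0
C[C>G]T	0.00906665	0.00182829	0.0025387	0.00305255	0
G[C>G]A	0.00890986	0.00239752	0.00151927	0.00269175	0
G[C>G]C	0.00785892	0.00119072	0.00242045	0.00106457	0
G[C>G]G	0.00722995	0.00209872	0.00262789	0.00158856	0
G[C>G]T	0.00797083	0.00211244	0.00205313	0.0019833	0
T[C>G]A	0.00691757	0.00153632	0.00340022	0.00182415	0
T[C>G]C	0.0062813	0.00138865	0.00252037	0.00166754	0
T[C>G]G	0.00769764	0.00120926	0.00196815	0.00154761	0
T[C>G]T	0.01093637	0.00134257	0.00168586	0.00123709	0
A[C>T]A	0.01090194	0.00160001	0.00951776	0.03603127	0.12360195
A[C>T]C	0.01167023	0.00144873	0.01341417	0.03634735	0.07579383
A[C>T]G	0.01463368	0.00206031	0.00874937	0.10717603	0.07187248
A[C>T]T	0.01630673	0.00186098	0.00910933	0.03271288	0.27314086
C[C>T]A	0.01290775	0.00154064	0.01145736	0.02149785	0.03300811
C[C>T]C	0.00943476	0.00218902	0.01504345	0.02852112	0.01555487
C[C>T]G	0.01106923	0.00182768	0.0165738	0.09302385	0.01944387
C[C>T]T	0.01156092	0.00231348	0.01100775	0.03057238	0.05220303
G[C>T]A	0.01189562	0.00157942	0.21805428	0.05457499	0.03261876
G[C>T]C	0.01087234	0.00199456	0.14207674	0.03404882	0.01617428
G[C>T]G	0.01255406	0.00164179	0.14585866	0.10772934	0.01253583
G[C>T]T	0.0083387	0.00138837	0.14788254	0.04657657	0.04653746
T[C>T]A	0.015528	0.00132337	0.00706805	0.02783334	0.04964019
T[C>T]C	0.01543482	0.00130402	0.01915745	0.0312535	0.03336747
T[C>T]G	0.01219502	0.00184	0.01439085	0.12905419	0.02484374
T[C>T]T	0.01077289	0.00204576	0.01388017	0.03190918	0.11966327
A[T>A]A	0.00927516	0.00157627	0.00317935	0.00169359	0
A[T>A]C	0.00544513	0.00140734	0.00222766	0.00193658	0
A[T>A]G	0.01031446	0.00122937	0.00262578	0.00138352	0
A[T>A]T	0.00681294	0.00171562	0.00149956	0.00198628	0
C[T>A]A	0.00931126	0.00144587	0.00236134	0.00166068	0
C[T>A]C	0.00972658	0.00161311	0.0033281	0.00191713	0
C[T>A]G	0.006999	0.00185237	0.00352766	0.00238146	0
C[T>A]T	0.00910246	0.0020684	0.00278883	0.00117531	0
G[T>A]A	0.00872445	0.0018524	0.00265211	0.00197228	0
G[T>A]C	0.00674111	0.00266356	0.00240701	0.00175628	0
G[T>A]G	0.00755129	0.0018025	0.00232673	0.00253811	0
G[T>A]T	0.00734121	0.00210337	0.00147804	0.00210532	0
T[T>A]A	0.00892507	0.00226739	0.0020486	0.00167744	0
T[T>A]C	0.00511589	0.00232971	0.00181943	0.00237683	0
T[T>A]G	0.00652242	0.00173551	0.00207913	0.00206701	0
T[T>A]T	0.00875419	0.00234399	0.00245928	0.00257694	0
A[T>C]A	0.01746418	0.00144035	0.002369	0.00108815	0
A[T>C]C	0.01553919	0.00162745	0.00378108	0.00165667	0
A[T>C]G	0.02075625	0.00160675	0.00206354	0.00125656	0
A[T>C]T	0.01208691	0.00154081	0.00306675	0.00208305	0
C[T>C]A	0.01521172	0.00142309	0.00222953	0.00182036	0
C[T>C]C	0.02742234	0.00159068	0.00256395	0.00213884	0
C[T>C]G	0.02504885	0.00192102	0.0013276	0.00145199	0
C[T>C]T	0.02029882	0.00182148	0.00273526	0.00109627	0
G[T>C]A	0.02524223	0.00140771	0.00363368	0.00116678	0
G[T>C]C	0.01950678	0.00179766	0.0029936	0.00115051	0
G[T>C]G	0.01477446	0.00153638	0.00194845	0.0010327	0
G[T>C]T	0.01569896	0.00250042	0.00256779	0.00211076	0
T[T>C]A	0.02222811	0.00224778	0.00272686	0.00277799	0
T[T>C]C	0.01580751	0.00135605	0.00323723	0.00137048	0
T[T>C]G	0.01241901	0.0021393	0.00234828	0.00184602	0
T[T>C]T	0.01610127	0.0015666	0.00376397	0.00230745	0
A[T>G]A	0.00726003	0.00206411	0.00155999	0.00239616	0
A[T>G]C	0.01094935	0.00230768	0.00281724	0.00316246	0
A[T>G]G	0.00732076	0.00118376	0.00162563	0.00186089	0
A[T>G]T	0.00820415	0.00148852	0.00231596	0.00185903	0
C[T>G]A	0.00559281	0.0017558	0.00275996	0.00162629	0
C[T>G]C	0.00757667	0.00159358	0.0016816	0.00221413	0
C[T>G]G	0.0063557	0.00199737	0.00369475	0.00260625	0
C[T>G]T	0.00792458	0.00207152	0.00323211	0.00114965	0
G[T>G]A	0.0081991	0.00221215	0.00334477	0.00223159	0
G[T>G]C	0.01080025	0.00228924	0.00288545	0.00178188	0
G[T>G]G	0.00804665	0.00239688	0.00207929	0.00230575	0
G[T>G]T	0.00771687	0.0018101	0.00243562	0.00171832	0
T[T>G]A	0.00807062	0.0019676	0.002003	0.00211802	0
T[T>G]C	0.00792491	0.00241186	0.00196536	0.00246623	0
T[T>G]G	0.00582915	0.00237318	0.00322464	0.00250443	0
T[T>G]T	0.00715709	0.00199303	0.00238041	0.00166475	0
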