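name	confirmed	fkh_activated	fkh1_sensitive	rdna
ARS0101	1	1	1	0
ARS0102	1	0	0	0
ARS0103	1	0	0	0
ARS0104	1	0	0	0
ARS0105	1	1	0	0
ARS0106	1	0	0	0
ARS0107	1	0	0	0
ARS0108	1	0	0	0
ARS0201	1	0	0	0
ARS0202	1	1	0	0
ARS0203	1	0	0	0
ARS0204	1	0	0	0
ARS0205	1	0	0	0
ARS0206	1	1	1	0
ARS0207	1	0	0	0
ARS0208	1	0	0	0
ARS0209	1	0	0	0
ARS0210	1	1	0	0
ARS0211	1	0	0	0
ARS0212	1	0	0	0
ARS0213	1	0	0	0
ARS0214	1	0	0	0
ARS0215	1	1	0	0
ARS0216	1	0	0	0
ARS0217	1	0	0	0
ARS0218	1	0	0	0
ARS0219	1	1	1	0
ARS0220	1	0	0	0
ARS0221	1	0	0	0
ARS0222	1	0	0	0
ARS0223	1	1	0	0
ARS0224	1	0	0	0
ARS0225	1	0	0	0
ARS0226	1	0	0	0
ARS0227	1	0	0	0
ARS0228	1	1	1	0
ARS0301	1	0	0	0
ARS0302	1	0	0	0
ARS0303	1	0	0	0
ARS0304	1	1	0	0
ARS0305	1	0	0	0
ARS0306	1	0	0	0
ARS0307	1	0	0	0
ARS0308	1	1	0	0
ARS0309	1	0	0	0
ARS0310	1	0	0	0
ARS0311	1	0	0	0
ARS0401	1	0	0	0
ARS0402	1	1	1	0
ARS0403	1	0	0	0
ARS0404	1	0	0	0
ARS0405	1	0	0	0
ARS0406	1	1	0	0
ARS0407	1	0	0	0
ARS0408	1	0	0	0
ARS0409	1	0	0	0
ARS0410	1	1	0	0
ARS0411	1	0	0	0
ARS0412	1	0	0	0
ARS0413	1	0	0	0
ARS0414	1	0	0	0
ARS0415	1	1	1	0
ARS0416	1	0	0	0
ARS0417	1	0	0	0
ARS0418	1	0	0	0
ARS0419	1	1	0	0
ARS0420	1	0	0	0
ARS0421	1	0	0	0
ARS0422	1	0	0	0
ARS0423	1	1	0	0
ARS0424	1	0	0	0
ARS0425	1	0	0	0
ARS0426	1	0	0	0
ARS0427	1	0	0	0
ARS0428	1	1	1	0
ARS0429	1	0	0	0
ARS0430	1	0	0	0
ARS0431	1	0	0	0
ARS0432	1	1	0	0
ARS0433	1	0	0	0
ARS0434	1	0	0	0
ARS0435	1	0	0	0
ARS0436	1	1	1	0
ARS0437	1	0	0	0
ARS0438	1	0	0	0
ARS0439	1	0	0	0
ARS0440	1	0	0	0
ARS0441	1	1	0	0
ARS0442	1	0	0	0
ARS0443	1	0	0	0
ARS0444	1	0	0	0
ARS0445	1	1	0	0
ARS0446	1	0	0	0
ARS0447	1	0	0	0
ARS0448	1	0	0	0
ARS0449	1	1	1	0
ARS0450	1	0	0	0
ARS0451	1	0	0	0
ARS0452	1	0	0	0
ARS0501	1	0	0	0
ARS0502	1	1	0	0
ARS0503	1	0	0	0
ARS0504	1	0	0	0
ARS0505	1	0	0	0
ARS0506	1	1	0	0
ARS0507	1	0	0	0
ARS0508	1	0	0	0
ARS0509	1	0	0	0
ARS0510	1	1	1	0
ARS0511	1	0	0	0
ARS0512	1	0	0	0
ARS0513	1	0	0	0
ARS0514	1	0	0	0
ARS0515	1	1	0	0
ARS0516	1	0	0	0
ARS0517	1	0	0	0
ARS0518	1	0	0	0
ARS0519	1	1	0	0
ARS0601	1	0	0	0
ARS0602	1	0	0	0
ARS0603	1	0	0	0
ARS0604	1	1	1	0
ARS0605	1	0	0	0
ARS0606	1	0	0	0
ARS0607	1	0	0	0
ARS0608	1	0	0	0
ARS0609	1	1	0	0
ARS0701	1	0	0	0
ARS0702	1	0	0	0
ARS0703	1	0	0	0
ARS0704	1	1	1	0
ARS0705	1	0	0	0
ARS0706	1	0	0	0
ARS0707	1	0	0	0
ARS0708	1	1	0	0
ARS0709	1	0	0	0
ARS0710	1	0	0	0
ARS0711	1	0	0	0
ARS0712	1	0	0	0
ARS0713	1	1	0	0
ARS0714	1	0	0	0
ARS0715	1	0	0	0
ARS0716	1	0	0	0
ARS0717	1	1	1	0
ARS0718	1	0	0	0
ARS0719	1	0	0	0
ARS0720	1	0	0	0
ARS0721	1	1	0	0
ARS0722	1	0	0	0
ARS0723	1	0	0	0
ARS0724	1	0	0	0
ARS0725	1	0	0	0
ARS0726	1	1	0	0
ARS0727	1	0	0	0
ARS0728	1	0	0	0
ARS0729	1	0	0	0
ARS0730	1	1	1	0
ARS0731	1	0	0	0
ARS0732	1	0	0	0
ARS0733	1	0	0	0
ARS0734	1	1	0	0
ARS0735	1	0	0	0
ARS0736	1	0	0	0
ARS0737	1	0	0	0
ARS0801	1	0	0	0
ARS0802	1	1	0	0
ARS0803	1	0	0	0
ARS0804	1	0	0	0
ARS0805	1	0	0	0
ARS0806	1	1	1	0
ARS0807	1	0	0	0
ARS0808	1	0	0	0
ARS0809	1	0	0	0
ARS0810	1	1	0	0
ARS0811	1	0	0	0
ARS0812	1	0	0	0
ARS0813	1	0	0	0
ARS0814	1	0	0	0
ARS0815	1	1	1	0
ARS0816	1	0	0	0
ARS0817	1	0	0	0
ARS0818	1	0	0	0
ARS0819	1	1	0	0
ARS0901	1	0	0	0
ARS0902	1	0	0	0
ARS0903	1	0	0	0
ARS0904	1	1	0	0
ARS0905	1	0	0	0
ARS0906	1	0	0	0
ARS0907	1	0	0	0
ARS0908	1	0	0	0
ARS0909	1	1	1	0
ARS0910	1	0	0	0
ARS0911	1	0	0	0
ARS0912	1	0	0	0
ARS0913	1	1	0	0
ARS0914	1	0	0	0
ARS0915	1	0	0	0
ARS1001	1	0	0	0
ARS1002	1	1	0	0
ARS1003	1	0	0	0
ARS1004	1	0	0	0
ARS1005	1	0	0	0
ARS1006	1	1	1	0
ARS1007	1	0	0	0
ARS1008	1	0	0	0
ARS1009	1	0	0	0
ARS1010	1	0	0	0
ARS1011	1	1	0	0
ARS1012	1	0	0	0
ARS1013	1	0	0	0
ARS1014	1	0	0	0
ARS1015	1	1	0	0
ARS1016	1	0	0	0
ARS1017	1	0	0	0
ARS1018	1	0	0	0
ARS1019	1	1	1	0
ARS1020	1	0	0	0
ARS1021	1	0	0	0
ARS1022	1	0	0	0
ARS1023	1	0	0	0
ARS1024	1	1	0	0
ARS1025	1	0	0	0
ARS1101	1	0	0	0
ARS1102	1	0	0	0
ARS1103	1	1	0	0
ARS1104	1	0	0	0
ARS1105	1	0	0	0
ARS1106	1	0	0	0
ARS1107	1	1	1	0
ARS1108	1	0	0	0
ARS1109	1	0	0	0
ARS1110	1	0	0	0
ARS1111	1	0	0	0
ARS1112	1	1	0	0
ARS1113	1	0	0	0
ARS1114	1	0	0	0
ARS1115	1	0	0	0
ARS1116	1	1	1	0
ARS1117	1	0	0	0
ARS1118	1	0	0	0
ARS1119	1	0	0	0
ARS1120	1	1	0	0
ARS1121	1	0	0	0
ARS1122	1	0	0	0
ARS1123	1	0	0	0
ARS1201	1	0	0	0
ARS1202	1	1	0	0
ARS1203	1	0	0	0
ARS1204	1	0	0	0
ARS1205	1	0	0	0
ARS1206	1	1	1	0
ARS1207	1	0	0	0
ARS1208	1	0	0	0
ARS1209	1	0	0	0
ARS1210	1	1	0	0
ARS1211	1	0	0	0
ARS1212	1	0	0	0
ARS1213	1	0	0	0
ARS1214	1	0	0	0
ARS1215	1	1	0	0
ARS1216	1	0	0	1
ARS1217	1	0	0	1
ARS1218	1	0	0	0
ARS1219	1	0	0	0
ARS1220	1	0	0	0
ARS1221	1	1	1	0
ARS1222	1	0	0	0
ARS1223	1	0	0	0
ARS1224	1	0	0	0
ARS1225	1	1	0	0
ARS1226	1	0	0	0
ARS1227	1	0	0	0
ARS1228	1	0	0	0
ARS1229	1	0	0	0
ARS1230	1	1	0	0
ARS1231	1	0	0	0
ARS1232	1	0	0	0
ARS1233	1	0	0	0
ARS1234	1	1	1	0
ARS1235	1	0	0	0
ARS1236	1	0	0	0
ARS1237	1	0	0	0
ARS1301	1	1	0	0
ARS1302	1	0	0	0
ARS1303	1	0	0	0
ARS1304	1	0	0	0
ARS1305	1	0	0	0
ARS1306	1	1	1	0
ARS1307	1	0	0	0
ARS1308	1	0	0	0
ARS1309	1	0	0	0
ARS1310	1	1	0	0
ARS1311	1	0	0	0
ARS1312	1	0	0	0
ARS1313	1	0	0	0
ARS1314	1	1	0	0
ARS1315	1	0	0	0
ARS1316	1	0	0	0
ARS1317	1	0	0	0
ARS1318	1	0	0	0
ARS1319	1	1	1	0
ARS1320	1	0	0	0
ARS1321	1	0	0	0
ARS1322	1	0	0	0
ARS1323	1	1	0	0
ARS1324	1	0	0	0
ARS1325	1	0	0	0
ARS1326	1	0	0	0
ARS1327	1	1	0	0
ARS1328	1	0	0	0
ARS1329	1	0	0	0
ARS1330	1	0	0	0
ARS1331	1	0	0	0
ARS1401	1	1	1	0
ARS1402	1	0	0	0
ARS1403	1	0	0	0
ARS1404	1	0	0	0
ARS1405	1	1	0	0
ARS1406	1	0	0	0
ARS1407	1	0	0	0
ARS1408	1	0	0	0
ARS1409	1	1	0	0
ARS1410	1	0	0	0
ARS1411	1	0	0	0
ARS1412	1	0	0	0
ARS1413	1	0	0	0
ARS1414	1	1	1	0
ARS1415	1	0	0	0
ARS1416	1	0	0	0
ARS1417	1	0	0	0
ARS1418	1	1	0	0
ARS1419	1	0	0	0
ARS1420	1	0	0	0
ARS1421	1	0	0	0
ARS1422	1	1	1	0
ARS1423	1	0	0	0
ARS1424	1	0	0	0
ARS1425	1	0	0	0
ARS1426	1	0	0	0
ARS1427	1	1	0	0
ARS1501	1	0	0	0
ARS1502	1	0	0	0
ARS1503	1	0	0	0
ARS1504	1	1	0	0
ARS1505	1	0	0	0
ARS1506	1	0	0	0
ARS1507	1	0	0	0
ARS1508	1	1	1	0
ARS1509	1	0	0	0
ARS1510	1	0	0	0
ARS1511	1	0	0	0
ARS1512	1	0	0	0
ARS1513	1	1	0	0
ARS1514	1	0	0	0
ARS1515	1	0	0	0
ARS1516	1	0	0	0
ARS1517	1	1	0	0
ARS1518	1	0	0	0
ARS1519	1	0	0	0
ARS1520	1	0	0	0
ARS1521	1	1	1	0
ARS1522	1	0	0	0
ARS1523	1	0	0	0
ARS1524	1	0	0	0
ARS1525	1	0	0	0
ARS1526	1	1	0	0
ARS1527	1	0	0	0
ARS1528	1	0	0	0
ARS1529	1	0	0	0
ARS1530	1	1	0	0
ARS1531	1	0	0	0
ARS1532	1	0	0	0
ARS1533	1	0	0	0
ARS1534	1	1	1	0
ARS1535	1	0	0	0
ARS1536	1	0	0	0
ARS1537	1	0	0	0
ARS1601	1	0	0	0
ARS1602	1	1	0	0
ARS1603	1	0	0	0
ARS1604	1	0	0	0
ARS1605	1	0	0	0
ARS1606	1	1	1	0
ARS1607	1	0	0	0
ARS1608	1	0	0	0
ARS1609	1	0	0	0
ARS1610	1	1	0	0
ARS1611	1	0	0	0
ARS1612	1	0	0	0
ARS1613	1	0	0	0
ARS1614	1	0	0	0
ARS1615	1	1	0	0
ARS1616	1	0	0	0
ARS1617	1	0	0	0
ARS1618	1	0	0	0
ARS1619	1	1	1	0
ARS1620	1	0	0	0
ARS1621	1	0	0	0
ARS1622	1	0	0	0
ARS1623	1	1	0	0
ARS1624	1	0	0	0
ARS1625	1	0	0	0
ARS1626	1	0	0	0
ARS1627	1	0	0	0
ARS1628	1	1	0	0
ARS1629	1	0	0	0
ARS1630	1	0	0	0
ARS1631	1	0	0	0
ARS1632	1	1	1	0
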