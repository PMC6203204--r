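# synthetic equine resting sinus rhythm with second-degree AV blocks (ms per line)
1605.687
1613.056
1657.925
1520.155
1666.528
1633.165
1545.436
1600.214
1591.277
1521.139
1580.479
3231.358
1594.110
1575.983
1576.584
1635.781
1544.241
1639.868
1592.871
1640.387
1624.854
1569.244
1581.880
1638.860
1642.741
1630.660
1665.937
1652.066
1705.981
1595.563
1653.560
1613.041
1612.565
1575.224
1560.697
1627.742
1611.414
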