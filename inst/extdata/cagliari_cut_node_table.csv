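node_id,additional_count,ca_pctl,second_size,cs_pctl,distance,d_pctl,combined,betweenness,betweenness_rank
1949,5,95.43,21,85.06,532.0,21.62,202.11,0.17130,2
2688,3,84.36,1,0.0,1997.8,45.17,129.53,0.06987,5
4383,2,65.38,1,0.0,1469.3,37.79,103.16,0.01674,9
6869,1,0.0,2,59.40,1684.5,41.48,100.88,0.05562,6
6889,1,0.0,1,0.0,2855.0,55.89,55.89,0.00980,11
6885,1,0.0,1,0.0,1806.8,43.41,43.41,0.00673,13
5541,1,0.0,1,0.0,1489.6,38.31,38.31,0.01513,10
5094,1,0.0,1,0.0,1039.6,30.40,30.40,0.07742,4
2712,1,0.0,1,0.0,952.3,28.30,28.30,0.19063,1
1607,1,0.0,1,0.0,860.3,26.36,26.36,0.03149,8
2638,1,0.0,1,0.0,681.1,23.90,23.90,0.08808,3
1604,1,0.0,1,0.0,0.0,0.0,0.00,0.00675,12
4579,1,0.0,1,0.0,0.0,0.0,0.00,0.04956,7
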