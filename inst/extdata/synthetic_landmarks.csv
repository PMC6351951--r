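patient_id,point_label,x,y
RP01,P0,0,0
RP01,P1,24.9254523690622,84.4485595938831
RP01,P2,0,349.401014763862
RP01,P3,16.9798203660175,97.2891118877512
RP01,P4,84.9099649184772,313.137096145256
RP01,P5,38.9984219218604,96.9171648093737
RP01,P6,160.856960848905,417.579881161802
RP01,P8,0,84.4485595938831
PP01,P0,0,0
PP01,P1,4.29640822223571,28.3056949193631
PP01,P2,0,90.0353768630885
PP01,P3,3.38713403604925,39.6279939902971
PP01,P4,0,90.0353768630885
PP01,P5,6.27292361296713,22.5107536762672
PP01,P6,1.2024501375854,62.7592493594755
PP01,P8,0,28.3056949193631
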