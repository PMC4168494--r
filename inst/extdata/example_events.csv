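segment_id,sensor,activity
1,Hall-Bathroom door,use toilet
1,Toilet Flush,use toilet
1,Toilet Flush,use toilet
1,Toilet Flush,use toilet
1,Hall-Bathroom door,use toilet
2,Plates cupboard,prepare dinner
2,Freezer,prepare dinner
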