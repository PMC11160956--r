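subject_id,eye,image_id,acquired_at,quality_pbad,DART,AutoMorph
S01,left,img001,2023-05-02T09:12:00,0.08,1.5273,1.4410
S01,left,img002,2023-05-02T09:15:00,0.12,1.5266,1.4472
S01,left,img003,2023-05-02T09:19:00,0.31,1.5291,1.4391
S01,left,img004,2023-05-09T10:02:00,0.06,1.5260,1.4445
S01,right,img005,2023-05-02T09:24:00,0.10,1.5488,1.4808
S01,right,img006,2023-05-02T09:28:00,0.55,1.5431,1.4629
S01,right,img007,2023-05-09T10:07:00,0.18,1.5469,1.4742
S01,right,img008,2023-05-09T10:11:00,0.22,1.5481,1.4791
S02,left,img009,2023-05-04T14:31:00,0.09,1.4992,1.4103
S02,left,img010,2023-05-04T14:35:00,0.87,1.4410,1.3227
S02,left,img011,2023-05-04T14:40:00,0.16,1.4987,1.4120
S02,left,img012,2023-05-04T14:44:00,0.27,1.4975,1.4061
S03,left,img013,2023-05-11T11:05:00,0.11,1.5121,1.4288
S03,left,img014,2023-05-11T11:09:00,0.19,1.5134,1.4330
S03,left,img015,2023-05-11T11:14:00,0.42,1.5110,1.4249
S03,left,img016,2023-05-11T11:18:00,0.13,1.5128,1.4307
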