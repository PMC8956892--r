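sample,DYS19,DYS385a,DYS385b,DYS389I,DYS389II,DYS390,DYS391,DYS392,DYS393,DYS437,DYS438,DYS439,DYS448,DYS456,DYS458,DYS635,YGATAH4,DYS481,DYS533,DYS549,DYS570,DYS576,DYS643
S001,10,13,18,15,31,22,10,12,12,16,12,12,21,18,18,20,10,25,14,11,19,21,10
S002,18,16,17,14,34,27,5,10,14,17,12,11,14,13,16,24,16,26,10,12,18,20,6
S003,12,14,19,15,31,21.1,9,13,10,14,13,11,19,18,18,20,9,27,13,10,19,20,10
S004,18,15,17,14,33,27,8,10,14,15,12,11,16,12,14,26,15,23,8,14,19,19,9
S005,18,16,17,13,34,26,9,9,15,17,13,11,15,12,15,25,14,24,10,15,16,18,10
S006,13,13,19,15,30,23,8,11,9,18,11,11,18,19,15,19,11,26,13,11,20,21,11
S007,11,11,17,14,29,23,8,12,12,16,15,11,20,18,17,20,12,26,13,12,19,18,9
S008,13,15,19,15,32,24,8,12,12,18,14,12,19,18,16,20,10,26,13,12,18,19,10
S009,19,12,17,11,31,22,7,10,13,14,11,15,18,16,19,27,10,27,8,9,18,20,8
S010,20,16,17,15,35,28,7,10,15,12,11,11,16,12,13,25,15,24,8,14,18,20,10
S011,16,11,20,13,32,26,13,12,13,12,13,12,21,15,14,26,9,27,12,15,21,20,12
S012,17,9,19,11,32,24,12,10,14,12,14,12,21,15,14,26,9,23,10,13,20,21,12
S013,17,15,17,14,32,28.1,5,11,17,15,14,13,16,12,14,23,16,24,10,15,18,20,9
S014,12,13,20,15,31,25,9,12,12,15,12,12,19,18,16,19,10,25,16,13,18,18,10
S015,18,10,20,10,33,26,13,12,15,12,12,12,21,15,12,26,9,26,13,15,20,20,12
S016,12,13,19,14,30,23,8,13,10,16,13,10,20,16,17,19,9,29.1,12,13,19,19,10
S017,13,14,19,14,30,23,9,12,11,14,12,12,18,15,16,19,10,29,13,11,19,18,9
S018,19,,,11,31,23,11,13,14,12,13,13,22,15,14,26,10,26,10,12,,20,13
S019,10,14,18,15,31,23.1,9,11,8,14,11,11,18,18,17,21,11,25,14,10,18,20,11
S020,18,12,13,12,32,21,8,11,13,15,12,13,17,13,18,27,11,26,10,10,17,20,9
S021,16,9,22,12,35,27,11,13,16,12,13,13,21,14,14,25,10,26,11,15,19,21,12
S022,18,10,19,11,30,25,12,12,11,12,12,11,22,14,16,26,9,26,10,15,21,21,14
S023,18,16,19,14,32,27,7,12,14,13,12,9,17,13,14,25,15,27,11,14,17,18,9
S024,18,15,17,14,33,25,7,9,14,16,12,11,17,11,16,23,15,22,9,15,17,21,9
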