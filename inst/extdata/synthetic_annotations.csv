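tweet_id,user_id,hashtag,class_value
t00001,u0001,tag00001_1,-1
t00001,u0001,tag00001_2,0
t00002,u0001,tag00002_1,0
t00002,u0001,tag00002_2,0
t00003,u0001,tag00003_1,0
t00003,u0001,tag00003_2,-3
t00004,u0002,tag00004_1,0
t00004,u0002,tag00004_2,-1
t00005,u0002,tag00005_1,1
t00005,u0002,tag00005_2,-1
t00006,u0002,tag00006_1,-1
t00006,u0002,tag00006_2,1
t00007,u0003,tag00007_1,-3
t00007,u0003,tag00007_2,-3
t00008,u0003,tag00008_1,-3
t00008,u0003,tag00008_2,0
t00009,u0003,tag00009_1,0
t00009,u0003,tag00009_2,-3
t00010,u0004,tag00010_1,-3
t00010,u0004,tag00010_2,0
t00011,u0004,tag00011_1,-3
t00011,u0004,tag00011_2,0
t00012,u0004,tag00012_1,0
t00012,u0004,tag00012_2,-3
t00013,u0005,tag00013_1,0
t00013,u0005,tag00013_2,1
t00014,u0005,tag00014_1,3
t00014,u0005,tag00014_2,0
t00015,u0005,tag00015_1,1
t00015,u0005,tag00015_2,3
t00016,u0006,tag00016_1,1
t00016,u0006,tag00016_2,3
t00017,u0006,tag00017_1,1
t00017,u0006,tag00017_2,1
t00018,u0006,tag00018_1,3
t00018,u0006,tag00018_2,1
t00019,u0007,tag00019_1,-3
t00019,u0007,tag00019_2,-1
t00020,u0007,tag00020_1,-3
t00020,u0007,tag00020_2,0
t00021,u0007,tag00021_1,-3
t00021,u0007,tag00021_2,0
t00022,u0008,tag00022_1,-3
t00022,u0008,tag00022_2,-1
t00023,u0008,tag00023_1,-3
t00023,u0008,tag00023_2,0
t00024,u0008,tag00024_1,-3
t00024,u0008,tag00024_2,-3
t00025,u0009,tag00025_1,3
t00025,u0009,tag00025_2,0
t00026,u0009,tag00026_1,1
t00026,u0009,tag00026_2,3
t00027,u0009,tag00027_1,3
t00027,u0009,tag00027_2,3
t00028,u0010,tag00028_1,3
t00028,u0010,tag00028_2,3
t00029,u0010,tag00029_1,3
t00029,u0010,tag00029_2,3
t00030,u0010,tag00030_1,0
t00030,u0010,tag00030_2,3
t00031,u0011,tag00031_1,3
t00031,u0011,tag00031_2,1
t00032,u0011,tag00032_1,0
t00032,u0011,tag00032_2,1
t00033,u0011,tag00033_1,3
t00033,u0011,tag00033_2,0
t00034,u0012,tag00034_1,3
t00034,u0012,tag00034_2,3
t00035,u0012,tag00035_1,1
t00035,u0012,tag00035_2,0
t00036,u0012,tag00036_1,0
t00036,u0012,tag00036_2,3
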