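site,month,replicate,m1,m2,m3,m4,m5,total
1,Sep,1,62,26,61,12,42,211
1,Sep,2,70,23,79,27,48,252
1,Sep,3,81,32,74,32,58,283
2,Sep,1,200,84,29,9,18,360
2,Sep,2,197,76,34,10,19,350
3,Sep,1,149,77,27,5,13,288
3,Sep,2,228,69,25,8,21,375
3,Sep,3,160,60,17,3,20,281
4,Oct,1,103,48,67,19,57,301
4,Oct,2,109,51,91,30,67,360
5,Oct,1,203,64,51,6,19,363
5,Oct,2,93,27,19,7,10,161
5,Oct,3,165,52,29,6,16,282
6,Oct,1,138,54,94,32,64,396
6,Oct,2,81,36,60,13,42,237
7,Oct,1,132,45,66,19,38,314
7,Oct,2,164,61,71,17,46,378
7,Oct,3,143,57,61,19,49,342
8,Oct,1,69,26,33,8,12,155
8,Oct,2,144,45,57,16,38,318
9,Sep,1,153,45,55,11,23,294
9,Sep,2,170,66,57,13,33,355
9,Sep,3,128,63,45,17,30,303
10,Sep,1,152,53,16,3,9,247
10,Sep,2,172,57,19,4,9,273
11,Sep,1,107,29,26,15,18,203
11,Sep,2,130,57,40,11,34,287
11,Sep,3,80,32,28,4,15,167
12,Sep,1,98,44,14,1,12,177
12,Sep,2,139,65,15,6,7,245
13,Sep,1,270,95,8,2,8,400
13,Sep,2,241,107,9,2,4,370
13,Sep,3,134,57,4,0,3,205
14,Sep,1,155,59,47,18,38,331
14,Sep,2,103,42,26,8,11,197
15,Sep,1,232,73,4,1,1,317
15,Sep,2,181,70,2,0,0,261
15,Sep,3,280,89,6,1,3,389
16,Sep,1,89,40,24,10,18,186
16,Sep,2,128,35,41,15,28,252
17,Sep,1,228,73,38,14,25,397
17,Sep,2,211,80,34,11,18,362
17,Sep,3,197,83,36,12,29,376
18,Sep,1,156,47,26,6,16,262
18,Sep,2,111,37,22,7,11,193
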