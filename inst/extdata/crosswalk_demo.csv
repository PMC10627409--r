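phecode_v12,phecode_x
427,CV_416
427.2,CV_416.2
410,CV_404
411,CV_404
414,CV_404.1
250,EM_202
250.1,EM_202.1
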